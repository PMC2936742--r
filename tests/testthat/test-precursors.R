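cycle_hg <- function() build_hypergraph(make_cycle_motif()$network)

test_that("plain scope excludes the cycle target; self-generation reaches it", {
  hg <- cycle_hg()
  sc <- scope(hg, c("s1", "s2"))
  expect_false("t" %in% sc$reached)
  expect_identical(sc$reached, c("s1", "s2"))
  expect_length(sc$fired, 0)

  ms <- maximal_self_generating_scope(hg, c("s1", "s2"))
  expect_true("t" %in% ms$scope$reached)
  expect_true("c1" %in% ms$Z)

  expect_error(scope(hg, "nope"), "unknown initial metabolite")
})

test_that("scope of the empty set is empty and fires nothing", {
  sc <- scope(cycle_hg(), character())
  expect_length(sc$reached, 0)
  expect_length(sc$fired, 0)
})

test_that("scope is order-independent (random single-firing oracle)", {
  for (s in 1:15) {
    gen <- random_network(generator_spec(n_metabolites = 10, n_reactions = 7,
                                         p_reversible = 0.2, seed = 4000 + s))
    hg <- build_hypergraph(gen$network)
    init <- gen$truth$nutrients
    ours <- sort(scope(hg, init)$reached)
    for (ord in 1:8) {
      expect_identical(scope_random_order(hg, init, seed = 100 * s + ord), ours)
    }
  }
})

test_that("scope is monotone and idempotent", {
  for (s in 1:20) {
    gen <- random_network(generator_spec(n_metabolites = 10, n_reactions = 8,
                                         p_reversible = 0.2, n_cycles = s %% 2,
                                         seed = 5000 + s))
    hg <- build_hypergraph(gen$network)
    v <- hg$vertices
    small <- withr::with_seed(s, sample(v, 2))
    big <- union(small, withr::with_seed(s + 1, sample(v, 2)))
    r_small <- scope(hg, small)$reached
    r_big <- scope(hg, big)$reached
    expect_true(all(r_small %in% r_big))
    expect_identical(sort(scope(hg, r_small)$reached), sort(r_small))
  }
})

test_that("self-generation adds nothing in the cycle-free limit", {
  for (s in 1:15) {
    gen <- random_network(generator_spec(n_metabolites = 10, n_reactions = 7,
                                         dag = TRUE, p_reversible = 0,
                                         seed = 6000 + s))
    hg <- build_hypergraph(gen$network)
    p <- withr::with_seed(s, sample(hg$vertices, 3))
    expect_identical(sort(maximal_self_generating_scope(hg, p)$scope$reached),
                     sort(scope(hg, p)$reached))
  }
})

test_that("precursor-set test matches the cycle motif semantics", {
  hg <- cycle_hg()
  ok <- is_precursor_set(hg, c("s1", "s2"), "t")
  expect_true(ok)
  wit <- attr(ok, "witness")
  expect_identical(check_witness(hg, wit), "ok")
  expect_false(is_precursor_set(hg, "s1", "t"))
  expect_false(is_precursor_set(hg, "s2", "t"))

  # a target inside P is trivially reachable; no borrow needed in a chain
  chain_hg <- build_hypergraph(make_chain_network())
  ok2 <- is_precursor_set(chain_hg, "A", "A")
  expect_true(ok2)
  expect_length(attr(ok2, "witness")$Z, 0)
})

test_that("borrowed metabolites that are consumed but not regenerated fail", {
  # s + c1 -> t + c2 with no way back from c2 to c1: using c1 "uses it up"
  net <- metabolic_network(
    c("s", "c1", "c2", "t"),
    bind_reactions(reaction("R1", c("s", "c1"), c("t", "c2")))
  )
  hg <- build_hypergraph(net)
  expect_false(is_precursor_set(hg, "s", "t"))
  expect_length(maximal_self_generating_scope(hg, "s")$Z, 0)
})

test_that("enumeration reproduces the motif ground truths", {
  hg <- cycle_hg()
  row <- enumerate_minimal_precursor_sets(hg, c("s1", "s2"), "t")
  expect_identical(solution_sets(row), list(c("s1", "s2")))
  expect_identical(row$status, "complete")

  pair <- make_reversible_pair_motif()
  hg2 <- build_hypergraph(pair$network)
  row2 <- enumerate_minimal_precursor_sets(hg2, c("A", "B"), "T")
  expect_identical(solution_sets(row2), list("A", "B"))

  # a target that is itself a seed
  row3 <- enumerate_minimal_precursor_sets(hg2, c("A", "B"), "A")
  expect_identical(solution_sets(row3), list("A", "B"))

  # unreachable target: empty solution list, not an error
  iso <- metabolic_network(c("u", "v", "w"),
                           bind_reactions(reaction("R1", "u", "v")))
  row4 <- enumerate_minimal_precursor_sets(build_hypergraph(iso), "u", "w")
  expect_length(row4$solutions, 0)
})

test_that("enumeration equals the brute-force oracle on random instances", {
  for (s in 1:40) {
    spec <- generator_spec(
      n_metabolites = withr::with_seed(s, sample(8:12, 1)),
      n_reactions = withr::with_seed(s + 1, sample(5:7, 1)),
      p_reversible = 0.15, f_nutrients = 0.35,
      n_cycles = s %% 3 == 0, seed = 7000 + s)
    gen <- random_network(spec)
    hg <- build_hypergraph(gen$network)
    seeds <- gen$truth$nutrients
    target <- withr::with_seed(s, sample(setdiff(hg$vertices, seeds), 1))
    fast <- enumerate_minimal_precursor_sets(hg, seeds, target)
    slow <- brute_force_minimal_precursor_sets(hg, seeds, target)
    expect_same_solution_sets(fast, slow)
    for (sol in fast$solutions) {
      expect_identical(check_witness(hg, sol), "ok")
    }
  }
})

test_that("precursor sets are closed under superset", {
  for (s in 1:15) {
    gen <- random_network(generator_spec(n_metabolites = 10, n_reactions = 7,
                                         f_nutrients = 0.4, n_cycles = s %% 2,
                                         seed = 8000 + s))
    hg <- build_hypergraph(gen$network)
    seeds <- gen$truth$nutrients
    target <- withr::with_seed(s, sample(setdiff(hg$vertices, seeds), 1))
    row <- enumerate_minimal_precursor_sets(hg, seeds, target)
    for (sol in row$solutions) {
      extras <- setdiff(seeds, sol$precursors)
      if (length(extras)) {
        expect_true(is_precursor_set(hg, c(sol$precursors, extras[1]), target))
      }
    }
  }
})

test_that("the brute-force oracle guards against oversized instances", {
  gen <- random_network(generator_spec(n_metabolites = 25, n_reactions = 10,
                                       seed = 1))
  hg <- build_hypergraph(gen$network)
  expect_error(brute_force_minimal_precursor_sets(hg, gen$truth$nutrients,
                                                  hg$vertices[25]),
               "too large")
})

test_that("the enumeration budget flags incomplete rows instead of truncating", {
  gen <- random_network(generator_spec(n_metabolites = 12, n_reactions = 10,
                                       f_nutrients = 0.5, seed = 99))
  hg <- build_hypergraph(gen$network)
  seeds <- gen$truth$nutrients
  target <- setdiff(hg$vertices, seeds)[1]
  row <- enumerate_minimal_precursor_sets(hg, seeds, target, max_tests = 1)
  expect_identical(row$status, "incomplete")
})

test_that("the precursor table computes S and P per the matrix definitions", {
  pair <- make_reversible_pair_motif()
  hg <- build_hypergraph(pair$network)
  tab <- precursor_table(hg, c("A", "B"), c("T", "B"))
  expect_identical(tab$S, c(2L, 2L))
  expect_identical(tab$P, c(2L, 2L))

  cyc <- make_cycle_motif()
  tab2 <- precursor_table(build_hypergraph(cyc$network), c("s1", "s2"), "t")
  expect_identical(tab2$S, 1L)
  expect_identical(tab2$P, 2L)

  m <- precursor_matrix(tab2)
  expect_identical(m$s1, 1L)
  expect_identical(m$s2, 1L)
  expect_identical(glance(tab2)$max_solutions, 1L)

  long <- tidy(tab)
  expect_identical(nrow(long), 4L)
  expect_s3_class(autoplot(tab), "ggplot")
})
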