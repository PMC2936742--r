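test_that("strongly connected components match hand cases", {
  two_cycle <- compound_graph(c("A", "B"),
                              tibble::tibble(from = c("A", "B"), to = c("B", "A")))
  expect_identical(strongly_connected_components(two_cycle), list(c("A", "B")))

  chain <- compound_graph(c("A", "B", "C"),
                          tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  expect_identical(strongly_connected_components(chain),
                   list("A", "B", "C"))
})

test_that("SCC partition agrees with the mutual-reachability oracle", {
  for (s in 1:25) {
    g <- random_digraph(n = sample(5:20, 1), p = stats::runif(1, 0.05, 0.3),
                        seed = 1000 + s)
    expect_identical(strongly_connected_components(g), scc_oracle(g))
  }
})

test_that("seed identification reproduces the motif behaviours", {
  pair <- make_reversible_pair_motif()
  rep <- identify_seeds(pair$network)
  expect_identical(rep$alternative_groups, list(c("A", "B")))
  expect_identical(rep$seeds, c("A", "B"))

  triple <- make_triple_motif()
  rep3 <- identify_seeds(triple$network)
  expect_identical(rep3$alternative_groups, list(c("gly", "ser", "thr")))
  expect_identical(rep3$seeds, sort(triple$truth$seeds))

  # directionality collapses the pair component to a single seed
  directed <- pair$network
  directed$reactions$reversible[1] <- FALSE
  expect_identical(identify_seeds(directed)$seeds, "A")

  chain <- make_chain_network()
  expect_identical(identify_seeds(chain)$seeds, "A")

  cyc <- make_cycle_motif()
  expect_identical(identify_seeds(cyc$network)$seeds, c("s1", "s2"))
})

test_that("tidy/glance expose the seed report as tables", {
  rep <- identify_seeds(make_triple_motif()$network)
  tab <- tidy(rep)
  expect_identical(sort(tab$seed), c("gly", "ser", "thr"))
  expect_true(all(tab$component_size == 3))
  expect_identical(glance(rep)$n_alternative_groups, 1L)
})

test_that("on acyclic networks seeds are exactly the in-degree-zero nodes", {
  for (s in 1:15) {
    gen <- random_network(generator_spec(n_metabolites = 12, n_reactions = 8,
                                         dag = TRUE, p_reversible = 0,
                                         seed = 2000 + s))
    rep <- identify_seeds(gen$network)
    g <- build_compound_graph(gen$network)
    never_produced <- setdiff(g$nodes, unique(g$arcs$to))
    expect_identical(rep$seeds, sort(never_produced))
    expect_true(all(lengths(rep$source_components) == 1))
  }
})

test_that("producing a seed from a non-seed removes it from the seed set", {
  net <- make_chain_network()  # seeds {A}
  plus <- net
  plus$reactions <- bind_reactions(plus$reactions, reaction("R3", "C", "A"))
  rep <- identify_seeds(plus)
  # A is now inside the A->B->C->A cycle: the whole loop is one source SCC
  expect_identical(rep$source_components, list(c("A", "B", "C")))

  ext <- metabolic_network(
    c("A", "B", "C", "D"),
    bind_reactions(reaction("R1", "A", "B"), reaction("R2", "B", "C"),
                   reaction("R3", "D", "A"))
  )
  expect_identical(identify_seeds(ext)$seeds, "D")
})

test_that("every node is reachable from some source component", {
  for (s in 1:15) {
    g <- random_digraph(n = 15, p = 0.12, seed = 3000 + s)
    parts <- strongly_connected_components(g)
    membership <- integer()
    for (i in seq_along(parts)) membership[parts[[i]]] <- i
    incoming <- rep(FALSE, length(parts))
    cf <- membership[g$arcs$from]; ct <- membership[g$arcs$to]
    incoming[unique(ct[cf != ct])] <- TRUE
    sources <- unlist(parts[!incoming])
    # BFS forward from the union of source components
    reached <- sources
    repeat {
      nxt <- setdiff(g$arcs$to[g$arcs$from %in% reached], reached)
      if (!length(nxt)) break
      reached <- c(reached, nxt)
    }
    expect_setequal(reached, g$nodes)
  }
})

test_that("classification flags partner production and list membership", {
  fix <- make_symbiosis_fixture()
  rep_a <- identify_seeds(fix$a)
  rep_b <- identify_seeds(fix$b)
  cls <- classify_seeds(rep_a, partner = fix$b,
                        host_list = c("asp"), transport_list = c("ser"))
  expect_setequal(cls$seed[cls$partner_produced],
                  fix$truth$a_seeds_produced_by_b)
  expect_identical(cls$seed[cls$host_or_diet], "asp")
  expect_identical(cls$seed[cls$transport_annotated], "ser")

  cls_b <- classify_seeds(rep_b, partner = fix$a)
  expect_setequal(cls_b$seed[cls_b$partner_produced],
                  fix$truth$b_seeds_produced_by_a)

  none <- classify_seeds(rep_a, partner = metabolic_network())
  expect_false(any(none$partner_produced))
})

test_that("seed set comparison is plain set algebra with optional synonyms", {
  fix <- make_symbiosis_fixture()
  cmp <- compare_seed_sets(identify_seeds(fix$a), identify_seeds(fix$b))
  expect_identical(cmp$common, fix$truth$common_seeds)

  same <- compare_seed_sets(identify_seeds(fix$a), identify_seeds(fix$a))
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)

  disjoint <- make_symbiosis_fixture(overlap = FALSE)
  cmp0 <- compare_seed_sets(identify_seeds(disjoint$a),
                            identify_seeds(disjoint$b))
  expect_length(cmp0$common, 0)

  # a synonym map reconciles the renamed ids
  syn <- c(ser_b = "ser", asp_b = "asp", bic_b = "bic")
  cmp_syn <- compare_seed_sets(identify_seeds(disjoint$a),
                               identify_seeds(disjoint$b), synonyms = syn)
  expect_identical(cmp_syn$common, c("asp", "bic", "ser"))

  expect_identical(nrow(tidy(cmp)), length(c(cmp$common, cmp$only_a, cmp$only_b)))
})
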