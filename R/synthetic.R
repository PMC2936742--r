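#' Canonical cycle motif (six metabolites, four reactions)
#'
#' The smallest network in which reaching the target requires borrowing and
#' regenerating a metabolite inside a cycle. Metabolites `s1`, `s2` (seeds),
#' `c1`, `c2` (the cycle), `i` (intermediate) and `t` (target); reactions
#' `R1: s1 + c1 -> c2 + i`, `R2: c2 -> c1`, `R3: i + s2 -> t`,
#' `R4: i -> c2`. The plain scope of `{s1, s2}` does not contain `t`;
#' allowing the self-generating metabolite `c1` (regenerated via `c2`)
#' makes `t` reachable, and `{s1, s2}` is the unique minimal precursor set
#' of `t`. This wiring is one canonical realization of the cycle semantics,
#' chosen for this package's fixtures.
#'
#' @return A list with `network` (a [metabolic_network()]) and `truth`
#'   (seeds, target, minimal precursor sets, a valid self-generating
#'   witness).
#' @export
make_cycle_motif <- function() {
  net <- metabolic_network(
    c("s1", "s2", "c1", "c2", "i", "t"),
    bind_reactions(
      reaction("R1", c("s1", "c1"), c("c2", "i")),
      reaction("R2", "c2", "c1"),
      reaction("R3", c("i", "s2"), "t"),
      reaction("R4", "i", "c2")
    ),
    provenance = "make_cycle_motif"
  )
  truth <- list(
    seeds = c("s1", "s2"),
    target = "t",
    minimal_precursor_sets = list(c("s1", "s2")),
    self_generating_witness = "c1",
    plain_scope_reaches_target = FALSE
  )
  list(network = net, truth = truth)
}

#' Reversible-pair motif (alternative seeds of size 2)
#'
#' Two metabolites `A` and `B` linked by one reversible reaction, neither
#' produced elsewhere, with `B` consumed downstream towards target `T`.
#' Both belong to one source component of size 2 and both are seeds; the
#' target has two alternative singleton minimal precursor sets, one per
#' member of the pair.
#'
#' @return A list with `network` and `truth`.
#' @export
make_reversible_pair_motif <- function() {
  net <- metabolic_network(
    c("A", "B", "T"),
    bind_reactions(
      reaction("R1", "A", "B", reversible = TRUE),
      reaction("R2", "B", "T")
    ),
    provenance = "make_reversible_pair_motif"
  )
  truth <- list(
    seeds = c("A", "B"),
    source_component = c("A", "B"),
    target = "T",
    minimal_precursor_sets = list("A", "B")
  )
  list(network = net, truth = truth)
}

#' Triple motif (alternative seeds of size 3)
#'
#' Three metabolites in one source strongly connected component via two
#' reversible reactions (the serine/glycine/threonine pattern), plus a
#' downstream consumer. All three are seeds and form one alternative group.
#'
#' @return A list with `network` and `truth`.
#' @export
make_triple_motif <- function() {
  net <- metabolic_network(
    c("ser", "gly", "thr", "x"),
    bind_reactions(
      reaction("R1", "ser", "gly", reversible = TRUE),
      reaction("R2", "thr", "gly", reversible = TRUE),
      reaction("R3", "gly", "x")
    ),
    provenance = "make_triple_motif"
  )
  truth <- list(
    seeds = c("gly", "ser", "thr"),
    source_component = c("gly", "ser", "thr"),
    target = "x",
    minimal_precursor_sets = list("gly", "ser", "thr")
  )
  list(network = net, truth = truth)
}

#' Specification for the random network generator
#'
#' @param n_metabolites,n_reactions Total counts (positive).
#' @param max_substrates,max_products Side arity bounds (at least 1).
#' @param p_reversible Probability that an eligible reaction is reversible
#'   (reactions touching a nutrient stay irreversible so nutrients are never
#'   produced).
#' @param f_nutrients Fraction of metabolites designated as nutrients
#'   (guaranteed seeds: no reaction produces them).
#' @param n_cycles Number of planted regeneration cycles (cycle-motif
#'   template embedded on reserved metabolites).
#' @param n_side_pairs Number of reactions carrying a planted ATP/ADP
#'   currency pair (for filtering fixtures).
#' @param dag If `TRUE`, force a topological order (guaranteed acyclic, all
#'   irreversible); incompatible with planted cycles.
#' @param seed Integer RNG seed; identical spec + seed give an identical
#'   network (the global RNG state is restored afterwards).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_metabolites = 12, n_reactions = 8,
                           max_substrates = 2, max_products = 2,
                           p_reversible = 0.1, f_nutrients = 0.25,
                           n_cycles = 0, n_side_pairs = 0, dag = FALSE,
                           seed = 1) {
  spec <- list(
    n_metabolites = as.integer(n_metabolites),
    n_reactions = as.integer(n_reactions),
    max_substrates = as.integer(max_substrates),
    max_products = as.integer(max_products),
    p_reversible = p_reversible, f_nutrients = f_nutrients,
    n_cycles = as.integer(n_cycles), n_side_pairs = as.integer(n_side_pairs),
    dag = isTRUE(dag), seed = as.integer(seed)
  )
  if (spec$n_metabolites < 1 || spec$n_reactions < 0) stop("counts must be positive")
  if (spec$max_substrates < 1 || spec$max_products < 1) stop("arity bounds must be >= 1")
  if (spec$p_reversible < 0 || spec$p_reversible > 1 ||
      spec$f_nutrients < 0 || spec$f_nutrients > 1) {
    stop("fractions must be in [0, 1]")
  }
  if (spec$dag && spec$n_cycles > 0) stop("dag = TRUE is incompatible with planted cycles")
  structure(spec, class = "generator_spec")
}

#' Generate a random metabolic network with known ground truth
#'
#' Builds a structurally valid network in which the designated nutrients
#' have no producing reaction (so they are guaranteed members of the seed
#' set), optionally embeds regeneration cycles following the cycle-motif
#' template on reserved metabolites (so each planted target is reachable
#' from its two nutrients only via a regenerated borrow, and its unique
#' minimal precursor set is known), and optionally plants ATP/ADP currency
#' pairs for filtering fixtures. Deterministic under `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A list with `network` and `truth` (`nutrients`, `cycles`,
#'   `n_side_occurrences`).
#' @export
random_network <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_metabolites
  if (spec$max_substrates + spec$max_products > n) {
    stop("infeasible spec: side arities exceed metabolite count")
  }
  n_nutr <- max(1L, round(spec$f_nutrients * n))
  if (spec$n_cycles > 0 && n_nutr < 2) {
    stop("infeasible spec: planted cycles need at least two nutrients")
  }
  n_random <- spec$n_reactions - 4L * spec$n_cycles
  if (n_random < 0) stop("infeasible spec: not enough reactions for planted cycles")
  mets <- sprintf("m%02d", seq_len(n))
  nutrients <- mets[seq_len(n_nutr)]
  free <- setdiff(mets, nutrients)
  if (4L * spec$n_cycles > length(free)) {
    stop("infeasible spec: not enough metabolites to embed planted cycles")
  }

  withr::with_seed(spec$seed, {
    rxn_rows <- list()
    cycles <- list()
    cycle_mets <- character()
    rid <- 0L
    next_id <- function() {
      rid <<- rid + 1L
      sprintf("R%02d", rid)
    }
    for (ci in seq_len(spec$n_cycles)) {
      cyc <- free[(4L * (ci - 1L) + 1L):(4L * ci)]  # c1, c2, i, t
      cycle_mets <- c(cycle_mets, cyc)
      ss <- sample(nutrients, 2)
      rxn_rows[[length(rxn_rows) + 1L]] <- bind_reactions(
        reaction(next_id(), c(ss[1], cyc[1]), c(cyc[2], cyc[3])),
        reaction(next_id(), cyc[2], cyc[1]),
        reaction(next_id(), c(cyc[3], ss[2]), cyc[4]),
        reaction(next_id(), cyc[3], cyc[2])
      )
      cycles[[ci]] <- list(
        seeds = sort(ss), target = cyc[4],
        minimal_precursor_sets = list(sort(ss))
      )
    }
    pool_sub <- setdiff(mets, cycle_mets)
    pool_prod <- setdiff(free, cycle_mets)
    if (n_random > 0 && length(pool_prod) == 0) {
      stop("infeasible spec: no metabolites left for random reaction products")
    }
    for (j in seq_len(n_random)) {
      ok <- FALSE
      for (try in 1:200) {
        ns <- sample.int(max(1L, min(spec$max_substrates, length(pool_sub) - 1L)), 1)
        sub <- sample(pool_sub, min(ns, length(pool_sub)))
        if (spec$dag) {
          hi <- max(match(sub, mets))
          cand <- pool_prod[match(pool_prod, mets) > hi]
        } else {
          cand <- setdiff(pool_prod, sub)
        }
        if (length(cand) == 0) next
        np <- sample(seq_len(min(spec$max_products, length(cand))), 1)
        prod <- sample(cand, np)
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible spec: could not place a random reaction")
      rev <- !spec$dag && !any(c(sub, prod) %in% nutrients) &&
        stats::runif(1) < spec$p_reversible
      rxn_rows[[length(rxn_rows) + 1L]] <- reaction(next_id(), sub, prod,
                                                    reversible = rev)
    }
    rxns <- dplyr::bind_rows(rxn_rows)
    n_side_occ <- 0L
    if (spec$n_side_pairs > 0) {
      if (spec$n_side_pairs > nrow(rxns)) {
        stop("infeasible spec: more side pairs than reactions")
      }
      pick <- sort(sample(seq_len(nrow(rxns)), spec$n_side_pairs))
      for (i in pick) {
        l <- c(rxns$left[[i]], ATP = 1)
        r <- c(rxns$right[[i]], ADP = 1)
        rxns$left[[i]] <- l[order(names(l))]
        rxns$right[[i]] <- r[order(names(r))]
      }
      mets <- c(mets, "ATP", "ADP")
      n_side_occ <- 2L * spec$n_side_pairs
    }
    net <- metabolic_network(mets, rxns,
                             provenance = sprintf("random_network seed=%d", spec$seed))
    list(
      network = net,
      truth = list(nutrients = nutrients, cycles = cycles,
                   n_side_occurrences = n_side_occ)
    )
  })
}

#' Two-organism fixture with planted cross-feeding
#'
#' Two small networks sharing an id space. With `overlap = TRUE` (default)
#' the seed sets share three metabolites (`ser`, `asp`, `bic`), organism B
#' produces two of A's seeds (`e4p`, `pep`) and organism A produces one of
#' B's seeds (`thr`); with `overlap = FALSE` the common seeds are renamed in
#' B so the seed sets are disjoint.
#'
#' @param overlap Logical.
#' @return A list with `a`, `b` (networks) and `truth` (`common_seeds`,
#'   `a_seeds_produced_by_b`, `b_seeds_produced_by_a`).
#' @export
make_symbiosis_fixture <- function(overlap = TRUE) {
  a <- metabolic_network(
    c("ser", "asp", "bic", "e4p", "pep", "i1", "trp", "hser", "thr", "oxa"),
    bind_reactions(
      reaction("A1", c("e4p", "pep"), "i1"),
      reaction("A2", c("i1", "ser"), "trp"),
      reaction("A3", c("asp", "bic"), "oxa"),
      reaction("A4", "asp", "hser"),
      reaction("A5", "hser", "thr")
    ),
    provenance = "make_symbiosis_fixture:A"
  )
  rename <- if (overlap) identity else function(x) {
    ifelse(x %in% c("ser", "asp", "bic"), paste0(x, "_b"), x)
  }
  b_mets <- rename(c("glc", "g6p", "e4p", "pep", "thr", "ser", "asp", "bic",
                     "met1", "oxa"))
  b <- metabolic_network(
    b_mets,
    bind_reactions(
      reaction("B1", "glc", "g6p"),
      reaction("B2", "g6p", "e4p"),
      reaction("B3", "g6p", "pep"),
      reaction("B4", rename(c("thr", "ser")), "met1"),
      reaction("B5", rename(c("asp", "bic")), "oxa")
    ),
    provenance = "make_symbiosis_fixture:B"
  )
  truth <- list(
    common_seeds = if (overlap) c("asp", "bic", "ser") else character(),
    a_seeds_produced_by_b = c("e4p", "pep"),
    b_seeds_produced_by_a = "thr"
  )
  list(a = a, b = b, truth = truth)
}
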