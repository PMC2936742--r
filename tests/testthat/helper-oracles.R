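# Independent oracles and small fixture builders shared across the suite.
# These deliberately avoid the package's own algorithms wherever they are
# used to check one.

# --- precursor-set helpers --------------------------------------------------

# the solution sets of a precursor row as a canonical list of sorted vectors
solution_sets <- function(row) {
  sets <- lapply(row$solutions, function(s) sort(s$precursors))
  sets[order(lengths(sets),
             vapply(sets, paste, "", collapse = "\r"))]
}

expect_same_solution_sets <- function(a, b) {
  expect_identical(solution_sets(a), solution_sets(b))
}

# all inclusion-minimal P subseteq seeds with target in the *plain* scope of
# P (no self-generation): the cycle-free reference answer
plain_scope_minimal_sets <- function(hg, seeds, target) {
  seeds <- sort(unique(seeds))
  accepted <- list()
  for (k in 0:length(seeds)) {
    subsets <- if (k == 0) list(character()) else
      apply(utils::combn(seeds, k), 2, identity, simplify = FALSE)
    for (p in subsets) {
      if (any(vapply(accepted, function(a) all(a %in% p), logical(1)))) next
      if (target %in% scope(hg, p)$reached) {
        accepted[[length(accepted) + 1L]] <- sort(p)
      }
    }
  }
  accepted[order(lengths(accepted),
                 vapply(accepted, paste, "", collapse = "\r"))]
}

# independent replay of a precursor_solution certificate: availability starts
# at P union Z, the fired hyperarcs must fire in order with all substrates
# available, the target must be reached and every z regenerated
check_witness <- function(hg, sol) {
  ha <- hg$hyperarcs
  avail <- c(sol$precursors, sol$Z)
  produced <- character()
  for (id in sol$fired) {
    i <- match(id, ha$id)
    if (is.na(i)) return("unknown fired hyperarc")
    if (!all(ha$substrates[[i]] %in% avail)) {
      return(paste0("hyperarc ", id, " fired without its substrates"))
    }
    avail <- union(avail, ha$products[[i]])
    produced <- union(produced, ha$products[[i]])
  }
  if (!(sol$target %in% avail)) return("target not reached")
  if (!all(sol$Z %in% produced)) return("self-generating metabolite not regenerated")
  if (length(intersect(sol$Z, sol$precursors))) return("Z overlaps P")
  "ok"
}

# --- strongly connected component oracle ------------------------------------

# O(n^2) mutual-reachability partition via boolean transitive closure
scc_oracle <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  reach <- diag(TRUE, n)
  dimnames(reach) <- list(nodes, nodes)
  for (i in seq_len(nrow(graph$arcs))) {
    reach[graph$arcs$from[i], graph$arcs$to[i]] <- TRUE
  }
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  groups <- unique(apply(mutual, 1, function(r) paste(nodes[r], collapse = "\r")))
  parts <- lapply(strsplit(groups, "\r", fixed = TRUE), sort)
  parts[order(lengths(parts), vapply(parts, `[`, "", 1))]
}

# random directed graph as a compound_graph
random_digraph <- function(n, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- stats::runif(nrow(pairs)) < p
    compound_graph(nodes, pairs[keep, ])
  })
}

# --- scope order-independence oracle ----------------------------------------

# repeatedly fire single random enabled hyperarcs until exhaustion; the
# resulting reached set must equal scope()'s for any order
scope_random_order <- function(hg, initial, seed) {
  withr::with_seed(seed, {
    ha <- hg$hyperarcs
    avail <- unique(initial)
    fired <- character()
    repeat {
      enabled <- which(vapply(seq_len(nrow(ha)), function(i) {
        !(ha$id[i] %in% fired) && all(ha$substrates[[i]] %in% avail)
      }, logical(1)))
      if (length(enabled) == 0) break
      i <- if (length(enabled) == 1) enabled else sample(enabled, 1)
      avail <- union(avail, ha$products[[i]])
      fired <- c(fired, ha$id[i])
    }
    sort(avail)
  })
}

# --- misc -------------------------------------------------------------------

# a small acyclic branched-pathway network used across several files
make_chain_network <- function() {
  metabolic_network(
    c("A", "B", "C"),
    bind_reactions(
      reaction("R1", "A", "B"),
      reaction("R2", "B", "C")
    )
  )
}
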