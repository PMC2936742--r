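## Internal integer-indexed form of a hypergraph, built once per search so
## the fixpoint kernel below runs on plain integer vectors.
hg_index <- function(hypergraph) {
  v <- hypergraph$vertices
  ha <- hypergraph$hyperarcs
  list(
    vnames = v,
    nv = length(v),
    ids = ha$id,
    sub = lapply(ha$substrates, match, table = v),
    prod = lapply(ha$products, match, table = v)
  )
}

## Least fixpoint of the firing rule: a hyperarc fires when all its
## substrates are available, adding all its products. Expansion proceeds in
## rounds; within a round every enabled hyperarc fires, in hyperarc list
## order, which makes the fired sequence deterministic. The reached set is
## order-independent (it is the unique least fixpoint).
scope_fixpoint <- function(idx, init) {
  avail <- logical(idx$nv)
  avail[init] <- TRUE
  remaining <- seq_along(idx$sub)
  fired <- integer(0)
  repeat {
    enabled <- remaining[vapply(remaining, function(j) all(avail[idx$sub[[j]]]),
                                logical(1))]
    if (length(enabled) == 0) break
    for (j in enabled) avail[idx$prod[[j]]] <- TRUE
    fired <- c(fired, enabled)
    remaining <- setdiff(remaining, enabled)
  }
  list(reached = which(avail), fired = fired)
}

products_of <- function(idx, fired) {
  if (length(fired) == 0) return(integer(0))
  sort(unique(unlist(idx$prod[fired])))
}

check_vertices <- function(hypergraph, ids, what) {
  unknown <- setdiff(ids, hypergraph$vertices)
  if (length(unknown)) {
    stop("unknown ", what, " metabolite(s): ", paste(unknown, collapse = ", "))
  }
}

scope_result <- function(idx, init, res) {
  structure(
    list(initial = sort(idx$vnames[init]),
         reached = idx$vnames[res$reached],
         fired = idx$ids[res$fired]),
    class = "scope_result"
  )
}

#' Scope (network expansion) of a metabolite set
#'
#' The scope of an initial set is the set itself plus any metabolite that
#' can be produced using only substrates already in the set, iterated until
#' no new compound can be produced (forward propagation on the reaction
#' hypergraph). A hyperarc fires only when *all* of its substrates are
#' available.
#'
#' @param hypergraph A [build_hypergraph()] result.
#' @param initial Character vector of metabolite ids (must be vertices).
#' @return A `scope_result`: `initial`, `reached` (sorted ids) and `fired`
#'   (hyperarc ids in deterministic firing order).
#' @export
scope <- function(hypergraph, initial) {
  check_vertices(hypergraph, initial, "initial")
  idx <- hg_index(hypergraph)
  init <- match(unique(initial), idx$vnames)
  scope_result(idx, init, scope_fixpoint(idx, init))
}

#' @export
print.scope_result <- function(x, ...) {
  cat("<scope_result> ", length(x$initial), " initial -> ",
      length(x$reached), " reached (", length(x$fired), " hyperarcs fired)\n",
      sep = "")
  invisible(x)
}

## Expansion with anchored borrowing: a hyperarc fires when every substrate
## is either genuinely available (seed-derived or already produced) or
## borrowable from z, AND at least one substrate is genuinely available.
## The anchor prevents closed borrow cycles (e.g. a lone reversible pair)
## from bootstrapping out of nothing: borrowed matter may only be drawn
## into an expansion that seed-derived matter is already driving. Borrowed
## metabolites enter the genuine set only once some fired hyperarc produces
## them. With z empty this is exactly scope_fixpoint.
anchored_fixpoint <- function(idx, p_int, z_int) {
  avail <- logical(idx$nv)
  avail[p_int] <- TRUE
  zset <- logical(idx$nv)
  zset[z_int] <- TRUE
  remaining <- seq_along(idx$sub)
  fired <- integer(0)
  repeat {
    enabled <- remaining[vapply(remaining, function(j) {
      s <- idx$sub[[j]]
      all(avail[s] | zset[s]) && any(avail[s])
    }, logical(1))]
    if (length(enabled) == 0) break
    for (j in enabled) avail[idx$prod[[j]]] <- TRUE
    fired <- c(fired, enabled)
    remaining <- setdiff(remaining, enabled)
  }
  # at the self-generating fixpoint every borrowed z is itself produced, so
  # reporting only genuinely available metabolites loses nothing there
  list(reached = which(avail), fired = fired)
}

## Greatest-fixpoint computation of the maximal self-generating set:
## Z0 = vertices \ P, then keep only the z that are products of hyperarcs
## fired in the anchored expansion from P borrowing Z, until stable.
msg_fixpoint <- function(idx, p_int) {
  z <- setdiff(seq_len(idx$nv), p_int)
  repeat {
    res <- anchored_fixpoint(idx, p_int, z)
    z_new <- intersect(z, products_of(idx, res$fired))
    if (length(z_new) == length(z)) {
      return(list(res = res, z = z))
    }
    z <- z_new
  }
}

#' Maximal self-generating expansion from a seed subset
#'
#' Cycles may require borrowing an internal metabolite to bootstrap the
#' expansion; the borrow is legitimate only if the metabolite is regenerated
#' (produced by a fired hyperarc) during the expansion itself. This function
#' computes the greatest fixpoint: starting from all non-P vertices as
#' candidate borrows, it repeatedly discards candidates that are not
#' regenerated, and returns the expansion from P plus the surviving
#' self-generating set Z*. Every member of the returned Z is a product of a
#' fired hyperarc of the returned expansion. In a cycle-free hypergraph the
#' reached set equals the plain [scope()] of P.
#'
#' Borrowing is *anchored*: a hyperarc may draw on borrowed metabolites only
#' when at least one of its substrates is genuinely available (a seed or
#' already produced). Without the anchor, a closed interconversion -- e.g. a
#' lone reversible reaction between two metabolites -- would count as
#' self-generating from an empty seed set, since each member is formally a
#' product of the other orientation's firing; anchoring restricts borrowing
#' to cycles that seed-derived matter actually drives.
#'
#' @param hypergraph A [build_hypergraph()] result.
#' @param p Character vector of metabolite ids.
#' @return A list with `scope` (a `scope_result` for P union Z) and `Z`
#'   (sorted character vector of self-generating metabolites).
#' @export
maximal_self_generating_scope <- function(hypergraph, p) {
  check_vertices(hypergraph, p, "initial")
  idx <- hg_index(hypergraph)
  p_int <- match(unique(p), idx$vnames)
  fp <- msg_fixpoint(idx, p_int)
  list(scope = scope_result(idx, c(p_int, fp$z), fp$res),
       Z = sort(idx$vnames[fp$z]))
}

## Certifying expansion that borrows lazily under the same anchored
## semantics as anchored_fixpoint: fire every hyperarc reachable without new
## borrows first, and only when stuck borrow (from the maximal
## self-generating set) the missing substrates of the first hyperarc that an
## anchored borrow would enable. The fired set ends up identical to the
## anchored expansion from P borrowing Z*, so every borrowed metabolite is
## regenerated, but the reported borrow set names only the metabolites the
## expansion really bootstraps on -- empty whenever plain scope suffices
## (e.g. acyclic hypergraphs).
witness_expansion <- function(idx, p_int, z_star) {
  avail <- logical(idx$nv)        # genuine: seeds and fired products
  avail[p_int] <- TRUE
  loaned <- logical(idx$nv)       # borrows taken so far
  zset <- logical(idx$nv)
  zset[setdiff(z_star, p_int)] <- TRUE
  remaining <- seq_along(idx$sub)
  fired <- integer(0)
  repeat {
    repeat {
      enabled <- remaining[vapply(remaining, function(j) {
        s <- idx$sub[[j]]
        all(avail[s] | loaned[s]) && any(avail[s])
      }, logical(1))]
      if (length(enabled) == 0) break
      for (j in enabled) avail[idx$prod[[j]]] <- TRUE
      fired <- c(fired, enabled)
      remaining <- setdiff(remaining, enabled)
    }
    cand <- remaining[vapply(remaining, function(j) {
      s <- idx$sub[[j]]
      all(avail[s] | loaned[s] | zset[s]) && any(avail[s])
    }, logical(1))]
    if (length(cand) == 0) break
    j <- cand[1]
    s <- idx$sub[[j]]
    loaned[s[!avail[s]]] <- TRUE
    avail[idx$prod[[j]]] <- TRUE
    fired <- c(fired, j)
    remaining <- setdiff(remaining, j)
  }
  list(fired = fired, borrowed = which(loaned))
}

precursor_solution <- function(target, precursors, z, fired) {
  structure(
    list(target = target, precursors = sort(precursors), Z = sort(z),
         fired = fired),
    class = "precursor_solution"
  )
}

#' @export
print.precursor_solution <- function(x, ...) {
  cat("<precursor_solution> target ", x$target, ": {",
      paste(x$precursors, collapse = ", "), "}",
      if (length(x$Z)) paste0("  [self-generating: ",
                              paste(x$Z, collapse = ", "), "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Test whether a seed subset is a precursor set of a target
#'
#' P is a precursor set of the target when there exists a set Z of
#' self-generating metabolites such that the expansion from P union Z
#' contains the target and all of Z (which ensures the regeneration of Z).
#' The test is performed with the maximal self-generating set; feasible Z
#' sets are closed under union, so the maximal one decides existence. When
#' true, a certifying `precursor_solution` is attached as attribute
#' `witness`; its `Z` lists the metabolites the certifying expansion
#' actually borrows (consumes before first producing), each of them
#' regenerated by a fired hyperarc. The full maximal set remains available
#' via [maximal_self_generating_scope()].
#'
#' @param hypergraph A [build_hypergraph()] result.
#' @param p Character vector of seed ids.
#' @param target A vertex id.
#' @return `TRUE` or `FALSE`, with attribute `witness` when `TRUE`.
#' @export
is_precursor_set <- function(hypergraph, p, target) {
  check_vertices(hypergraph, p, "initial")
  check_vertices(hypergraph, target, "target")
  idx <- hg_index(hypergraph)
  p_int <- match(unique(p), idx$vnames)
  fp <- msg_fixpoint(idx, p_int)
  ok <- match(target, idx$vnames) %in% fp$res$reached
  if (ok) {
    w <- witness_expansion(idx, p_int, fp$z)
    attr(ok, "witness") <- precursor_solution(
      target, unique(p), idx$vnames[w$borrowed], idx$ids[w$fired])
  }
  ok
}

## backward reachability on the arc projection of the hypergraph: which
## vertices can reach the target through some chain of hyperarcs
ancestors_of <- function(hypergraph, target) {
  ha <- hypergraph$hyperarcs
  if (nrow(ha) == 0) return(character())
  seen <- target
  frontier <- target
  while (length(frontier)) {
    hit <- vapply(ha$products, function(p) any(p %in% frontier), logical(1))
    nxt <- setdiff(unique(unlist(ha$substrates[hit])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setdiff(seen, target)
}

new_precursor_row <- function(target, solutions, status) {
  ord <- order(lengths(lapply(solutions, `[[`, "precursors")),
               vapply(solutions, function(s) paste(s$precursors, collapse = "\r"),
                      character(1)))
  structure(
    list(target = target, solutions = solutions[ord], status = status),
    class = "precursor_row"
  )
}

#' @export
print.precursor_row <- function(x, ...) {
  cat("<precursor_row> target ", x$target, ": ", length(x$solutions),
      " minimal precursor set(s) [", x$status, "]\n", sep = "")
  for (s in x$solutions) print(s)
  invisible(x)
}

#' Enumerate all minimal precursor sets of a target
#'
#' Returns every inclusion-minimal subset P of the seeds such that
#' [is_precursor_set()] holds — covering all alternative routes to the
#' target. The search restricts candidate seeds to ancestors of the target
#' (plus the target itself if it is a seed) and traverses the subset lattice
#' by increasing cardinality, pruning supersets of accepted solutions; this
#' is exact because precursor sets are closed under superset. Solutions are
#' canonically ordered by size, then lexicographically.
#'
#' @param hypergraph A [build_hypergraph()] result.
#' @param seeds Character vector of seed ids (subset of vertices).
#' @param target A vertex id.
#' @param max_tests Optional budget on the number of candidate subsets
#'   tested; when exceeded the row is returned with status `"incomplete"`
#'   instead of silently truncating.
#' @return A `precursor_row`: `target`, `solutions` (list of
#'   `precursor_solution`) and `status` (`"complete"`/`"incomplete"`). A
#'   target unreachable from all seeds yields an empty solution list.
#' @export
enumerate_minimal_precursor_sets <- function(hypergraph, seeds, target,
                                             max_tests = Inf) {
  check_vertices(hypergraph, seeds, "seed")
  check_vertices(hypergraph, target, "target")
  seeds <- sort(unique(seeds))
  candidates <- sort(intersect(seeds, c(ancestors_of(hypergraph, target), target)))
  idx <- hg_index(hypergraph)
  t_int <- match(target, idx$vnames)

  accepted <- list()      # integer index vectors into `candidates`
  solutions <- list()
  status <- "complete"
  tests <- 0L
  nc <- length(candidates)
  for (k in 0:nc) {
    subsets <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(nc, k), 2)
    for (s in subsets) {
      s <- as.integer(s)
      if (any(vapply(accepted, function(a) all(a %in% s), logical(1)))) next
      tests <- tests + 1L
      if (tests > max_tests) {
        status <- "incomplete"
        break
      }
      p_ids <- candidates[s]
      p_int <- match(p_ids, idx$vnames)
      fp <- msg_fixpoint(idx, p_int)
      if (t_int %in% fp$res$reached) {
        accepted[[length(accepted) + 1L]] <- s
        w <- witness_expansion(idx, p_int, fp$z)
        solutions[[length(solutions) + 1L]] <- precursor_solution(
          target, p_ids, idx$vnames[w$borrowed], idx$ids[w$fired])
      }
    }
    if (status == "incomplete") break
  }
  new_precursor_row(target, solutions, status)
}

## all subsets of `pool` (integer vector) of size k, as a list
int_subsets <- function(pool, k) {
  if (k == 0) return(list(integer(0)))
  if (length(pool) < k) return(list())
  lapply(asplit(utils::combn(length(pool), k), 2),
         function(j) pool[as.integer(j)])
}

#' Brute-force oracle for minimal precursor sets
#'
#' Verification oracle: enumerates every subset P of the seeds and, for each
#' P, searches every candidate self-generating set Z (subsets of the
#' vertices outside P that are products of at least one hyperarc — a
#' metabolite never produced by any hyperarc can never be regenerated).
#' P is accepted when some Z is fully regenerated in the expansion from
#' P union Z with the target reached; the inclusion-minimal accepted P are
#' returned. Exponential; guarded to at most 15 seeds and 20 vertices.
#'
#' @inheritParams enumerate_minimal_precursor_sets
#' @return A `precursor_row`.
#' @export
brute_force_minimal_precursor_sets <- function(hypergraph, seeds, target) {
  if (length(unique(seeds)) > 15 || length(hypergraph$vertices) > 20) {
    stop("instance too large for the brute-force oracle (max 15 seeds, 20 vertices)")
  }
  check_vertices(hypergraph, seeds, "seed")
  check_vertices(hypergraph, target, "target")
  seeds <- sort(unique(seeds))
  idx <- hg_index(hypergraph)
  t_int <- match(target, idx$vnames)
  seed_int <- match(seeds, idx$vnames)
  vprod <- sort(unique(unlist(idx$prod)))

  accepted <- list()
  witnesses <- list()
  for (k in 0:length(seed_int)) {
    for (p_int in int_subsets(seed_int, k)) {
      zpool <- setdiff(vprod, p_int)
      # monotone upper bound: anchored borrowing of every candidate at once
      ub <- anchored_fixpoint(idx, p_int, zpool)
      if (!(t_int %in% c(ub$reached, p_int))) next
      found <- NULL
      for (kz in 0:length(zpool)) {
        for (z in int_subsets(zpool, kz)) {
          res <- anchored_fixpoint(idx, p_int, z)
          if (t_int %in% c(res$reached) &&
              all(z %in% products_of(idx, res$fired))) {
            found <- list(z = z, res = res)
            break
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) {
        accepted[[length(accepted) + 1L]] <- p_int
        witnesses[[length(witnesses) + 1L]] <- precursor_solution(
          target, idx$vnames[p_int], idx$vnames[found$z], idx$ids[found$res$fired])
      }
    }
  }
  minimal <- vapply(seq_along(accepted), function(i) {
    !any(vapply(seq_along(accepted), function(j) {
      j != i && length(accepted[[j]]) < length(accepted[[i]]) &&
        all(accepted[[j]] %in% accepted[[i]])
    }, logical(1)))
  }, logical(1))
  new_precursor_row(target, witnesses[minimal], "complete")
}

#' Minimal precursor sets for a list of targets
#'
#' One row per target (single-target semantics). Column `S` counts the
#' minimal precursor sets (solutions) of the target; column `P` counts the
#' distinct precursors in the union of all its solutions.
#'
#' @inheritParams enumerate_minimal_precursor_sets
#' @param targets Character vector of target metabolite ids.
#' @return A `precursor_table` tibble with columns `target`, `S`, `P`,
#'   `status` and a `solutions` list column; the seed list is kept in
#'   attribute `seeds`.
#' @export
precursor_table <- function(hypergraph, seeds, targets, max_tests = Inf) {
  rows <- lapply(targets, function(t) {
    enumerate_minimal_precursor_sets(hypergraph, seeds, t, max_tests = max_tests)
  })
  out <- tibble::tibble(
    target = vapply(rows, `[[`, "", "target"),
    S = vapply(rows, function(r) length(r$solutions), integer(1)),
    P = vapply(rows, function(r) {
      length(unique(unlist(lapply(r$solutions, `[[`, "precursors"))))
    }, integer(1)),
    status = vapply(rows, `[[`, "", "status"),
    solutions = lapply(rows, `[[`, "solutions")
  )
  attr(out, "seeds") <- sort(unique(seeds))
  class(out) <- c("precursor_table", class(out))
  out
}

#' Tidy a precursor table
#' @param x A `precursor_table`.
#' @param ... Unused.
#' @return A long tibble with one row per (target, solution, precursor).
#' @method tidy precursor_table
#' @export
tidy.precursor_table <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    sols <- x$solutions[[i]]
    purrr::map_dfr(seq_along(sols), function(j) {
      tibble::tibble(target = x$target[i], solution = j,
                     precursor = sols[[j]]$precursors)
    })
  })
}

#' @method glance precursor_table
#' @export
glance.precursor_table <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x),
    max_solutions = if (nrow(x)) max(x$S) else 0L,
    max_precursors = if (nrow(x)) max(x$P) else 0L,
    all_complete = all(x$status == "complete")
  )
}

#' Targets-by-seeds presence/absence matrix
#'
#' The machine-readable precursor figure: one row per target, one 0/1
#' column per seed (1 when the seed occurs in at least one minimal
#' precursor set of the target), plus the `S` and `P` columns.
#'
#' @param table A [precursor_table()].
#' @return A wide tibble.
#' @export
precursor_matrix <- function(table) {
  seeds <- attr(table, "seeds")
  pres <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    used <- unique(unlist(lapply(table$solutions[[i]], `[[`, "precursors")))
    tibble::as_tibble(stats::setNames(as.list(as.integer(seeds %in% used)), seeds))
  })
  dplyr::bind_cols(table[, c("target", "S", "P")], pres)
}

#' Plot a precursor table as a target-by-seed tile matrix
#' @param object A [precursor_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot precursor_table
#' @export
autoplot.precursor_table <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::distinct(.data$target, .data$precursor)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$precursor, y = .data$target)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::labs(x = "seed", y = "target") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
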