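#' Strongly connected components of a compound graph
#'
#' Partition of the nodes into maximal mutually reachable sets. Singleton
#' nodes, including isolated ones, are components of their own.
#'
#' @param graph A [compound_graph()].
#' @return A list of character vectors (each sorted; list ordered by size
#'   then first member), forming a partition of the nodes.
#' @export
strongly_connected_components <- function(graph) {
  if (length(graph$nodes) == 0) return(list())
  comp <- igraph::components(cg_igraph(graph), mode = "strong")
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(unname(parts), sort)
  parts[order(lengths(parts), vapply(parts, `[`, "", 1))]
}

#' Identify seeds as source components of the compound graph
#'
#' Builds the compound graph, condenses it by strongly connected components
#' and returns the components with no incoming arc from outside themselves
#' (source components). Every member of a source component is reported as a
#' seed; components with two or more members are kept as "alternative seed"
#' groups (mutually interconverted metabolites, any of which could be the
#' actually imported one). Self-loops and arcs inside a component do not
#' count as incoming.
#'
#' Seed identification deliberately runs on the compound graph, not the
#' hypergraph: strongly connected components have no clear hypergraph
#' counterpart. The network should already be filtered to its
#' carbon-transfer core; this is the caller's responsibility.
#'
#' @param network A [metabolic_network()].
#' @return A `seed_report`: list with `source_components` (list of character
#'   vectors), `seeds` (their union, sorted), `alternative_groups`
#'   (components with >= 2 members) and `components` (the full partition).
#' @export
identify_seeds <- function(network) {
  graph <- build_compound_graph(network)
  parts <- strongly_connected_components(graph)
  membership <- integer(0)
  for (i in seq_along(parts)) {
    membership[parts[[i]]] <- i
  }
  incoming <- rep(FALSE, length(parts))
  if (nrow(graph$arcs) > 0) {
    cf <- membership[graph$arcs$from]
    ct <- membership[graph$arcs$to]
    cross <- cf != ct
    incoming[unique(ct[cross])] <- TRUE
  }
  sources <- parts[!incoming]
  structure(
    list(
      source_components = sources,
      seeds = sort(unique(unlist(sources))),
      alternative_groups = sources[lengths(sources) >= 2],
      components = parts
    ),
    class = "seed_report"
  )
}

#' @export
print.seed_report <- function(x, ...) {
  cat("<seed_report> ", length(x$seeds), " seeds in ",
      length(x$source_components), " source components (",
      length(x$alternative_groups), " alternative groups)\n", sep = "")
  invisible(x)
}

#' Tidy a seed report
#' @param x A `seed_report`.
#' @param ... Unused.
#' @return A tibble with columns `seed`, `component`, `component_size`.
#' @method tidy seed_report
#' @export
tidy.seed_report <- function(x, ...) {
  if (length(x$source_components) == 0) {
    return(tibble::tibble(seed = character(), component = integer(),
                          component_size = integer()))
  }
  purrr::map_dfr(seq_along(x$source_components), function(i) {
    tibble::tibble(seed = x$source_components[[i]], component = i,
                   component_size = length(x$source_components[[i]]))
  }) |> dplyr::arrange(.data$seed)
}

#' @method glance seed_report
#' @export
glance.seed_report <- function(x, ...) {
  tibble::tibble(
    n_seeds = length(x$seeds),
    n_source_components = length(x$source_components),
    n_alternative_groups = length(x$alternative_groups)
  )
}

#' Classify seeds against a partner network and literature lists
#'
#' For each seed, reports whether it can be produced by the partner
#' organism's network (the seed is in the product set of at least one
#' directed hyperarc of the partner's hypergraph), whether it is reported as
#' provided by the host or its diet, and whether a transport reaction is
#' annotated for it. The host/diet and transporter flags are lookups in
#' user-supplied lists; the package derives neither.
#'
#' @param report A `seed_report`.
#' @param partner A [metabolic_network()] filtered the same way, or `NULL`.
#' @param host_list,transport_list Character vectors of metabolite ids.
#' @return A tibble (`seed_classification`) with columns `seed`,
#'   `partner_produced`, `host_or_diet`, `transport_annotated`.
#' @export
classify_seeds <- function(report, partner = NULL, host_list = character(),
                           transport_list = character()) {
  produced <- character()
  if (!is.null(partner) && nrow(partner$reactions) > 0) {
    hg <- build_hypergraph(partner)
    produced <- unique(unlist(hg$hyperarcs$products))
  }
  out <- tibble::tibble(
    seed = report$seeds,
    partner_produced = report$seeds %in% produced,
    host_or_diet = report$seeds %in% host_list,
    transport_annotated = report$seeds %in% transport_list
  )
  class(out) <- c("seed_classification", class(out))
  out
}

#' Compare the seed sets of two organisms
#'
#' Plain set algebra on the two seed unions after applying an optional
#' synonym map (named character vector: `alias -> canonical id`) to both
#' sides. There is no fuzzy matching: unmapped id mismatches stay distinct.
#'
#' @param report_a,report_b `seed_report`s.
#' @param synonyms Optional named character vector reconciling ids across
#'   the two networks.
#' @return A `seed_comparison`: list with `common`, `only_a`, `only_b`
#'   (sorted character vectors).
#' @export
compare_seed_sets <- function(report_a, report_b, synonyms = NULL) {
  canon <- function(ids) {
    if (is.null(synonyms)) return(ids)
    mapped <- synonyms[ids]
    sort(unique(ifelse(is.na(mapped), ids, mapped)))
  }
  a <- canon(report_a$seeds)
  b <- canon(report_b$seeds)
  structure(
    list(common = sort(intersect(a, b)),
         only_a = sort(setdiff(a, b)),
         only_b = sort(setdiff(b, a))),
    class = "seed_comparison"
  )
}

#' @export
print.seed_comparison <- function(x, ...) {
  cat("<seed_comparison> common: ", length(x$common), "; only A: ",
      length(x$only_a), "; only B: ", length(x$only_b), "\n", sep = "")
  invisible(x)
}

#' Tidy a seed comparison
#' @param x A `seed_comparison`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `status`
#'   (`common` / `only_a` / `only_b`).
#' @method tidy seed_comparison
#' @export
tidy.seed_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(id = x$common, status = "common"),
    tibble::tibble(id = x$only_a, status = "only_a"),
    tibble::tibble(id = x$only_b, status = "only_b")
  )
}

#' Write the machine-readable seed table
#'
#' One row per seed with its source component and classification flags.
#'
#' @param report A `seed_report`.
#' @param classification Optional `seed_classification` for the same report.
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_seed_table <- function(report, classification = NULL, path) {
  tab <- tidy(report)
  if (!is.null(classification)) {
    tab <- dplyr::left_join(tab, classification, by = "seed")
  }
  readr::write_tsv(tab, path)
  invisible(tab)
}
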