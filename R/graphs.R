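#' Directed compound graph of a network
#'
#' Nodes are metabolites; there is an arc from u to v when at least one
#' reaction produces v from u (for each reaction, an arc from every left
#' metabolite to every right metabolite; reversible reactions also
#' contribute every right-to-left arc). Arcs are a set: parallel duplicates
#' collapse. Metabolites in no reaction become isolated nodes. A metabolite
#' appearing on both sides of a reaction induces a self-loop, which matters
#' for strongly connected component membership.
#'
#' Stoichiometric coefficients are deliberately discarded in this view (and
#' in the hypergraph view): the analysis is purely topological and
#' stoichiometric pruning is out of scope.
#'
#' @param network A [metabolic_network()].
#' @return A `compound_graph`: list with `nodes` (character vector) and
#'   `arcs` (tibble `from`, `to`).
#' @export
build_compound_graph <- function(network) {
  rxns <- network$reactions
  arcs <- purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    l <- names(rxns$left[[i]]); r <- names(rxns$right[[i]])
    fwd <- tidyr::expand_grid(from = l, to = r)
    if (rxns$reversible[i]) {
      dplyr::bind_rows(fwd, tidyr::expand_grid(from = r, to = l))
    } else fwd
  })
  if (nrow(arcs) == 0) arcs <- tibble::tibble(from = character(), to = character())
  arcs <- dplyr::arrange(dplyr::distinct(arcs), .data$from, .data$to)
  compound_graph(network$metabolites$id, arcs)
}

#' Construct a compound graph directly
#' @param nodes Character vector of node ids.
#' @param arcs Tibble with columns `from`, `to`; endpoints must be nodes.
#' @return A `compound_graph`.
#' @export
compound_graph <- function(nodes, arcs) {
  arcs <- tibble::as_tibble(arcs)
  bad <- setdiff(unique(c(arcs$from, arcs$to)), nodes)
  if (length(bad)) stop("arc endpoint(s) not in nodes: ", paste(bad, collapse = ", "))
  arcs <- dplyr::arrange(dplyr::distinct(arcs), .data$from, .data$to)
  structure(list(nodes = sort(unique(nodes)), arcs = arcs),
            class = "compound_graph")
}

#' @export
print.compound_graph <- function(x, ...) {
  cat("<compound_graph> ", length(x$nodes), " nodes, ", nrow(x$arcs),
      " arcs\n", sep = "")
  invisible(x)
}

cg_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$arcs, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}

#' Directed reaction hypergraph of a network
#'
#' Each irreversible reaction contributes one forward hyperarc (substrate
#' set to product set); each reversible reaction contributes a forward and a
#' backward hyperarc, so both orientations are simultaneously available
#' during scope expansion. Coefficients are dropped (set semantics).
#'
#' @param network A [metabolic_network()]; reaction sides must be non-empty.
#' @return A `reaction_hypergraph`: list with `vertices` (character) and
#'   `hyperarcs` (tibble `id`, `substrates`, `products` list columns,
#'   `reaction`, `orientation`).
#' @export
build_hypergraph <- function(network) {
  rxns <- network$reactions
  rows <- purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    l <- sort(names(rxns$left[[i]])); r <- sort(names(rxns$right[[i]]))
    if (length(l) == 0 || length(r) == 0) {
      stop("reaction ", rxns$id[i], " has an empty side; filter or validate first")
    }
    fwd <- tibble::tibble(
      id = paste0(rxns$id[i], "_f"), substrates = list(l), products = list(r),
      reaction = rxns$id[i], orientation = "forward"
    )
    if (rxns$reversible[i]) {
      dplyr::bind_rows(fwd, tibble::tibble(
        id = paste0(rxns$id[i], "_b"), substrates = list(r), products = list(l),
        reaction = rxns$id[i], orientation = "backward"
      ))
    } else fwd
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(id = character(), substrates = list(),
                           products = list(), reaction = character(),
                           orientation = character())
  }
  structure(list(vertices = sort(network$metabolites$id), hyperarcs = rows),
            class = "reaction_hypergraph")
}

#' @export
print.reaction_hypergraph <- function(x, ...) {
  cat("<reaction_hypergraph> ", length(x$vertices), " vertices, ",
      nrow(x$hyperarcs), " hyperarcs\n", sep = "")
  invisible(x)
}

#' Export a compound graph
#'
#' `edgelist` writes a two-column TSV (`from`, `to`); `graphml` writes a
#' GraphML document loadable by Cytoscape and igraph. Output is
#' deterministic: arcs are canonically ordered.
#'
#' @param graph A `compound_graph`.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_compound_graph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    readr::write_tsv(graph$arcs, path)
  } else {
    igraph::write_graph(cg_igraph(graph), path, format = "graphml")
  }
  invisible(path)
}
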