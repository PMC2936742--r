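#' Extract the sub-network certifying a precursor solution
#'
#' Starts from the hyperarcs fired in the solution's certifying expansion
#' and prunes, to a fixpoint, those that neither lie upstream of the target
#' nor are needed to regenerate a self-generating metabolite that is still
#' borrowed by a retained hyperarc. Regeneration machinery is kept even when
#' it is not on a simple path to the target: without it the certificate
#' would be invalid. The result is the bipartite metabolite/reaction graph
#' of the surviving hyperarcs with roles assigned from the solution.
#'
#' @param hypergraph The [build_hypergraph()] result the solution came from.
#' @param solution A `precursor_solution`.
#' @return A `subnetwork`: list of `nodes` (tibble `id`, `kind`, `role`) and
#'   `links` (tibble `from`, `to`, `type` in `substrate-of`/`produces`).
#' @export
extract_subnetwork <- function(hypergraph, solution) {
  ha <- hypergraph$hyperarcs
  keep_ids <- solution$fired
  target <- solution$target
  repeat {
    sub <- ha[ha$id %in% keep_ids, ]
    z_used <- intersect(solution$Z, unique(unlist(sub$substrates)))
    # backward closure of useful hyperarcs from the target and borrowed z
    useful_mets <- c(target, z_used)
    useful_arcs <- character()
    repeat {
      hit <- vapply(seq_len(nrow(sub)), function(i) {
        !(sub$id[i] %in% useful_arcs) && any(sub$products[[i]] %in% useful_mets)
      }, logical(1))
      if (!any(hit)) break
      useful_arcs <- c(useful_arcs, sub$id[hit])
      useful_mets <- unique(c(useful_mets, unlist(sub$substrates[hit])))
    }
    kept <- intersect(keep_ids, useful_arcs)
    if (length(kept) == length(keep_ids)) break
    keep_ids <- kept
  }

  sub <- ha[ha$id %in% keep_ids, ]
  # one reaction node per origin reaction (both orientations collapse)
  links <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    dplyr::bind_rows(
      tibble::tibble(from = sub$substrates[[i]], to = sub$reaction[i],
                     type = "substrate-of"),
      tibble::tibble(from = sub$reaction[i], to = sub$products[[i]],
                     type = "produces")
    )
  })
  if (nrow(links) == 0) {
    links <- tibble::tibble(from = character(), to = character(),
                            type = character())
  }
  links <- dplyr::arrange(dplyr::distinct(links),
                          .data$from, .data$to, .data$type)
  mets <- sort(unique(unlist(c(sub$substrates, sub$products, target))))
  z_used <- intersect(solution$Z, unique(unlist(sub$substrates)))
  role <- dplyr::case_when(
    mets == target ~ "target",
    mets %in% solution$precursors ~ "precursor",
    mets %in% z_used ~ "self-generating",
    TRUE ~ "intermediate"
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = mets, kind = "metabolite", role = role),
    tibble::tibble(id = sort(unique(sub$reaction)), kind = "reaction",
                   role = "reaction")
  )
  structure(list(nodes = nodes, links = links), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("<subnetwork> ", sum(x$nodes$kind == "metabolite"), " metabolites, ",
      sum(x$nodes$kind == "reaction"), " reactions, ", nrow(x$links),
      " links\n", sep = "")
  invisible(x)
}

#' Export a sub-network for Cytoscape
#'
#' `SIF` writes one line per link with interaction types `substrate-of` and
#' `produces`; `GraphML` writes node attributes `kind` (metabolite or
#' reaction) and `role` (precursor, self-generating, intermediate, target).
#' Output is deterministic: nodes and links are canonically ordered.
#'
#' @param sub A [extract_subnetwork()] result.
#' @param path Output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
export_subnetwork <- function(sub, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- sprintf("%s\t%s\t%s", sub$links$from, sub$links$type, sub$links$to)
    writeLines(lines, path)
  } else {
    doc <- xml2::xml_new_root(
      "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
    for (key in c("kind", "role")) {
      xml2::xml_add_child(doc, "key", id = key, `for` = "node",
                          attr.name = key, attr.type = "string")
    }
    g <- xml2::xml_add_child(doc, "graph", id = "subnetwork",
                             edgedefault = "directed")
    for (i in seq_len(nrow(sub$nodes))) {
      n <- xml2::xml_add_child(g, "node", id = sub$nodes$id[i])
      d <- xml2::xml_add_child(n, "data", key = "kind")
      xml2::xml_text(d) <- sub$nodes$kind[i]
      d <- xml2::xml_add_child(n, "data", key = "role")
      xml2::xml_text(d) <- sub$nodes$role[i]
    }
    for (i in seq_len(nrow(sub$links))) {
      xml2::xml_add_child(g, "edge", source = sub$links$from[i],
                          target = sub$links$to[i], label = sub$links$type[i])
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Render the summary report files
#'
#' Writes the machine-readable seed table(s), the common/specific seed
#' partition (two-organism mode), the targets-by-seeds precursor matrix per
#' organism, and a plain-text summary of headline counts. All outputs are
#' TSV with canonical ordering, so reruns on identical inputs are
#' byte-identical.
#'
#' @param seed_reports Named list of `seed_report`s (one per organism).
#' @param classifications Optional named list of `seed_classification`s.
#' @param comparison Optional `seed_comparison` (two-organism mode).
#' @param precursor_tables Optional named list of [precursor_table()]s.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
render_summary <- function(seed_reports, classifications = NULL,
                           comparison = NULL, precursor_tables = NULL,
                           dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  summary_lines <- character()
  for (org in names(seed_reports)) {
    rep <- seed_reports[[org]]
    path <- file.path(dir, paste0("seeds_", org, ".tsv"))
    write_seed_table(rep, classifications[[org]], path)
    written <- c(written, path)
    summary_lines <- c(summary_lines, sprintf(
      "%s: %d seeds in %d source components (%d alternative groups)",
      org, length(rep$seeds), length(rep$source_components),
      length(rep$alternative_groups)))
  }
  if (!is.null(comparison)) {
    path <- file.path(dir, "seed_comparison.tsv")
    readr::write_tsv(tidy(comparison), path)
    written <- c(written, path)
    summary_lines <- c(summary_lines, sprintf(
      "common seeds: %d; specific: %d / %d",
      length(comparison$common), length(comparison$only_a),
      length(comparison$only_b)))
  }
  for (org in names(precursor_tables)) {
    tab <- precursor_tables[[org]]
    path <- file.path(dir, paste0("precursors_", org, ".tsv"))
    readr::write_tsv(precursor_matrix(tab), path)
    written <- c(written, path)
    g <- glance(tab)
    summary_lines <- c(summary_lines, sprintf(
      "%s precursors: %d targets, max S = %d, max P = %d",
      org, g$n_targets, g$max_solutions, g$max_precursors))
  }
  path <- file.path(dir, "summary.txt")
  writeLines(summary_lines, path)
  written <- c(written, path)
  invisible(written)
}

#' Write precursor solutions as JSON
#'
#' One record per target with its status and solutions (precursors,
#' self-generating set, fired hyperarcs).
#'
#' @param table A [precursor_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_precursor_json <- function(table, path) {
  rlang::check_installed("jsonlite")
  recs <- lapply(seq_len(nrow(table)), function(i) {
    list(
      target = table$target[i],
      status = table$status[i],
      solutions = lapply(table$solutions[[i]], function(s) {
        list(precursors = s$precursors, self_generating = s$Z, fired = s$fired)
      })
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
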