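#' Read a pipeline configuration
#'
#' YAML with per-organism input SBML paths and the shared resources:
#'
#' ```yaml
#' organisms:
#'   orgA: {sbml: a.xml, targets: targets_a.txt, seeds: null}
#'   orgB: {sbml: b.xml}
#' side_compound_rules: rules.csv   # optional; package default when absent
#' inorganics: [WATER, PROTON]      # optional; package default when absent
#' host_list: host.txt              # optional id list files
#' transport_list: transport.txt
#' synonyms: {alias: canonical}     # optional id reconciliation map
#' out_dir: results
#' max_tests: 100000                # optional enumeration budget
#' ```
#'
#' Referenced files must exist at read time; organisms must be uniquely
#' named.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("configured file does not exist: ", p)
    p
  }
  if (is.null(cfg$organisms) || length(cfg$organisms) < 1) {
    stop("config needs at least one organism")
  }
  if (anyDuplicated(names(cfg$organisms))) stop("organism names must be unique")
  for (org in names(cfg$organisms)) {
    cfg$organisms[[org]]$sbml <- resolve(cfg$organisms[[org]]$sbml)
    cfg$organisms[[org]]$targets <- resolve(cfg$organisms[[org]]$targets)
    cfg$organisms[[org]]$seeds <- resolve(cfg$organisms[[org]]$seeds)
  }
  cfg$side_compound_rules <- resolve(cfg$side_compound_rules)
  cfg$host_list <- resolve(cfg$host_list)
  cfg$transport_list <- resolve(cfg$transport_list)
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  if (is.null(cfg$max_tests)) cfg$max_tests <- Inf
  structure(cfg, class = "pipeline_config")
}

read_id_list <- function(path) {
  if (is.null(path)) return(character())
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

config_rules <- function(config) {
  if (is.null(config$side_compound_rules)) default_side_compound_rules()
  else read_side_compound_rules(config$side_compound_rules)
}

config_inorganics <- function(config) {
  if (is.null(config$inorganics)) inorganic_compounds()
  else as.character(config$inorganics)
}

#' Filter stage of the pipeline
#'
#' Reads each organism's SBML, applies the carbon-core filtering pass and
#' writes the filtered SBML plus the removal log.
#'
#' @param config A [read_pipeline_config()] result (or equivalent list).
#' @return Named list of `filter_result`s, invisibly; files are written to
#'   `out_dir`.
#' @export
run_filter <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- config_rules(config)
  inorg <- config_inorganics(config)
  out <- list()
  for (org in names(config$organisms)) {
    net <- read_sbml(config$organisms[[org]]$sbml)
    res <- filter_network(net, rules = rules, inorganic_ids = inorg)
    write_sbml(res$network, file.path(config$out_dir,
                                      paste0(org, "_filtered.xml")),
               model_id = org)
    write_removal_log(res$log, file.path(config$out_dir,
                                         paste0(org, "_removal_log.tsv")))
    out[[org]] <- res
  }
  invisible(out)
}

#' Seed stage of the pipeline
#'
#' Identifies seeds per organism on the filtered networks, classifies them
#' against the partner network (two-organism mode) and the host/transport
#' lists, and writes the seed tables and comparison.
#'
#' @param config A pipeline config.
#' @param filtered Optional named list of filtered networks (output of
#'   [run_filter()]); recomputed when absent.
#' @return A list with `reports`, `classifications`, `comparison` (NULL in
#'   single-organism mode), invisibly.
#' @export
run_seeds <- function(config, filtered = NULL) {
  if (is.null(filtered)) filtered <- run_filter(config)
  orgs <- names(config$organisms)
  host <- read_id_list(config$host_list)
  transport <- read_id_list(config$transport_list)
  reports <- lapply(filtered, function(f) identify_seeds(f$network))
  classifications <- list()
  for (org in orgs) {
    partner <- if (length(orgs) == 2) filtered[[setdiff(orgs, org)]]$network else NULL
    classifications[[org]] <- classify_seeds(reports[[org]], partner, host, transport)
  }
  comparison <- NULL
  if (length(orgs) == 2) {
    syn <- if (is.null(config$synonyms)) NULL else unlist(config$synonyms)
    comparison <- compare_seed_sets(reports[[orgs[1]]], reports[[orgs[2]]], syn)
  }
  render_summary(reports, classifications, comparison, dir = config$out_dir)
  invisible(list(reports = reports, classifications = classifications,
                 comparison = comparison))
}

#' Precursor stage of the pipeline
#'
#' Enumerates minimal precursor sets for each organism's target list
#' (seeds default to the seed stage's output, overridable by a seed id
#' file) and writes the precursor matrix, the solution JSON and the
#' certifying sub-network exports.
#'
#' @param config A pipeline config.
#' @param filtered,seed_stage Optional precomputed stage outputs.
#' @return Named list of [precursor_table()]s, invisibly.
#' @export
run_precursors <- function(config, filtered = NULL, seed_stage = NULL) {
  if (is.null(filtered)) filtered <- run_filter(config)
  if (is.null(seed_stage)) seed_stage <- run_seeds(config, filtered)
  tables <- list()
  for (org in names(config$organisms)) {
    ocfg <- config$organisms[[org]]
    targets <- read_id_list(ocfg$targets)
    if (length(targets) == 0) next
    net <- filtered[[org]]$network
    hg <- build_hypergraph(net)
    seeds <- if (!is.null(ocfg$seeds)) read_id_list(ocfg$seeds)
             else seed_stage$reports[[org]]$seeds
    tab <- precursor_table(hg, seeds, targets, max_tests = config$max_tests)
    tables[[org]] <- tab
    readr::write_tsv(precursor_matrix(tab),
                     file.path(config$out_dir, paste0("precursors_", org, ".tsv")))
    write_precursor_json(tab, file.path(config$out_dir,
                                        paste0("precursors_", org, ".json")))
    for (i in seq_len(nrow(tab))) {
      for (j in seq_along(tab$solutions[[i]])) {
        sub <- extract_subnetwork(hg, tab$solutions[[i]][[j]])
        export_subnetwork(sub, file.path(
          config$out_dir,
          sprintf("subnetwork_%s_%s_%d.sif", org, tab$target[i], j)), "SIF")
      }
    }
  }
  invisible(tables)
}

#' Simulation stage: write generated fixtures
#'
#' Generates a random network from a [generator_spec()] and writes the SBML
#' plus the ground truth as JSON.
#'
#' @param spec A [generator_spec()].
#' @param out_dir Output directory.
#' @param name Basename for the two files.
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(spec = generator_spec(), out_dir = ".",
                         name = "simulated") {
  rlang::check_installed("jsonlite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- random_network(spec)
  sbml <- file.path(out_dir, paste0(name, ".xml"))
  truth <- file.path(out_dir, paste0(name, "_truth.json"))
  write_sbml(gen$network, sbml, model_id = name)
  jsonlite::write_json(gen$truth, truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(sbml, truth))
}

#' Run the full pipeline
#'
#' Filter, seeds and precursors in order; a complete audit trail (filtered
#' SBML, removal logs, seed tables, comparison, precursor matrix/JSON,
#' sub-network exports, summary) is left in `out_dir`. Reruns on identical
#' inputs are byte-identical.
#'
#' @param config A pipeline config (or path to one).
#' @return A list with all stage outputs, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  filtered <- run_filter(config)
  seed_stage <- run_seeds(config, filtered)
  tables <- run_precursors(config, filtered, seed_stage)
  render_summary(seed_stage$reports, seed_stage$classifications,
                 seed_stage$comparison, tables, dir = config$out_dir)
  invisible(list(filtered = filtered, seeds = seed_stage, precursors = tables))
}
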