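#' Read a metabolic network from SBML
#'
#' Minimal reader for the SBML Level 2 / Level 3 core subset used for
#' small-molecule metabolic networks: one model, `listOfSpecies`,
#' `listOfReactions` with `speciesReference` stoichiometries. Compartments,
#' kinetic laws, rules, events and the fbc extension are ignored. The
#' stoichiometry attribute defaults to 1 when omitted; the `reversible`
#' attribute defaults to `TRUE` (the Level 2 default) when omitted.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_network()]. Species order and reaction order are
#'   preserved from the file.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  models <- xml2::xml_find_all(doc, "/sbml/model")
  if (length(models) != 1) {
    stop("SBML file must contain exactly one model: ", path)
  }
  model <- models[[1]]

  sp <- xml2::xml_find_all(model, "./listOfSpecies/species")
  ids <- xml2::xml_attr(sp, "id")
  if (any(is.na(ids))) stop("species without id in ", path)
  nm <- xml2::xml_attr(sp, "name")
  mets <- tibble::tibble(
    id = ids,
    name = ifelse(is.na(nm), ids, nm),
    is_inorganic = FALSE,
    notes = ""
  )
  if (anyDuplicated(mets$id)) {
    stop("duplicate species id in ", path, ": ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }

  rx <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  read_side <- function(r, what) {
    refs <- xml2::xml_find_all(r, paste0("./", what, "/speciesReference"))
    species <- xml2::xml_attr(refs, "species")
    st <- xml2::xml_attr(refs, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    stats::setNames(st, species)
  }
  rows <- lapply(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    rev <- xml2::xml_attr(r, "reversible")
    left <- read_side(r, "listOfReactants")
    right <- read_side(r, "listOfProducts")
    unknown <- setdiff(c(names(left), names(right)), mets$id)
    if (length(unknown)) {
      stop("reaction ", rid, " references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
    tibble::tibble(
      id = rid,
      left = list(left[order(names(left))]),
      right = list(right[order(names(right))]),
      reversible = is.na(rev) || identical(rev, "true"),
      direction_evidence = "unassigned",
      notes = ""
    )
  })
  rxns <- dplyr::bind_rows(rows)
  if (nrow(rxns) > 0 && anyDuplicated(rxns$id)) {
    stop("duplicate reaction id in ", path, ": ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  metabolic_network(mets, if (nrow(rxns)) rxns else NULL,
                    provenance = paste0("read_sbml:", basename(path)))
}

#' Write a metabolic network to SBML
#'
#' Emits SBML Level 3 Version 1 core with one compartment. The emitted file
#' re-reads with [read_sbml()] to a network equal (ids, sides, coefficients,
#' reversibility) to the one written; output is deterministic byte-for-byte
#' for a given network.
#'
#' @param network A [metabolic_network()]; must pass [validate_network()].
#' @param path Output file path.
#' @param model_id Model id attribute.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path, model_id = "model") {
  v <- validate_network(network)
  if (length(v)) {
    stop("network fails validation: ", paste(v, collapse = "; "))
  }
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1"
  )
  model <- xml2::xml_add_child(doc, "model", id = model_id)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")

  los <- xml2::xml_add_child(model, "listOfSpecies")
  mets <- network$metabolites
  for (i in seq_len(nrow(mets))) {
    xml2::xml_add_child(
      los, "species", id = mets$id[i], name = mets$name[i],
      compartment = "c", hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false"
    )
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  rxns <- network$reactions
  for (i in seq_len(nrow(rxns))) {
    r <- xml2::xml_add_child(
      lor, "reaction", id = rxns$id[i],
      reversible = if (rxns$reversible[i]) "true" else "false",
      fast = "false"
    )
    add_side <- function(node, side, what) {
      lst <- xml2::xml_add_child(node, what)
      for (j in seq_along(side)) {
        xml2::xml_add_child(
          lst, "speciesReference", species = names(side)[j],
          stoichiometry = format(unname(side[j]), scientific = FALSE),
          constant = "true"
        )
      }
    }
    add_side(r, rxns$left[[i]], "listOfReactants")
    add_side(r, rxns$right[[i]], "listOfProducts")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
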