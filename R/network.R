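#' Construct a metabolic network
#'
#' A `metabolic_network` holds a table of metabolites and a table of
#' reactions. Reaction sides are stored as named numeric vectors in list
#' columns (names are metabolite ids, values are positive stoichiometric
#' coefficients). Compartments are not modelled: all species are treated as a
#' single pool, which is appropriate for single-compartment bacterial
#' small-molecule metabolism. Metabolite identity is the id string (names are
#' kept for display only), because ids are the only stable join key across
#' files.
#'
#' @param metabolites A tibble with at least an `id` column, or a character
#'   vector of ids. Optional columns: `name`, `is_inorganic`, `notes`.
#' @param reactions A tibble of reactions as built by [reaction()] /
#'   [bind_reactions()], or `NULL` for an empty network. Required columns:
#'   `id`, `left`, `right`, `reversible`. Optional: `direction_evidence`
#'   (one of `"metacyc_pathway"`, `"topological"`, `"unassigned"`), `notes`.
#' @param provenance Free-text provenance (source file, curation log).
#'
#' @return An object of class `metabolic_network`.
#' @export
#' @examples
#' net <- metabolic_network(
#'   c("A", "B", "C"),
#'   bind_reactions(
#'     reaction("R1", c("A", "B"), "C"),
#'     reaction("R2", "C", "A", reversible = TRUE)
#'   )
#' )
#' net
metabolic_network <- function(metabolites = character(), reactions = NULL,
                              provenance = "") {
  mets <- as_metabolite_tbl(metabolites)
  rxns <- as_reaction_tbl(reactions)
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  structure(
    list(metabolites = mets, reactions = rxns, provenance = provenance),
    class = "metabolic_network"
  )
}

as_metabolite_tbl <- function(x) {
  if (is.character(x)) {
    x <- tibble::tibble(id = x)
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) > 0 && !("id" %in% names(x))) stop("metabolites need an `id` column")
  if (!("id" %in% names(x))) x$id <- character()
  if (!("name" %in% names(x))) x$name <- x$id
  if (!("is_inorganic" %in% names(x))) x$is_inorganic <- FALSE
  if (!("notes" %in% names(x))) x$notes <- ""
  x[, c("id", "name", "is_inorganic", "notes")]
}

as_reaction_tbl <- function(x) {
  if (is.null(x)) {
    return(tibble::tibble(
      id = character(), left = list(), right = list(),
      reversible = logical(), direction_evidence = character(),
      notes = character()
    ))
  }
  x <- tibble::as_tibble(x)
  need <- c("id", "left", "right", "reversible")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("reactions missing column(s): ", paste(miss, collapse = ", "))
  if (!("direction_evidence" %in% names(x))) x$direction_evidence <- "unassigned"
  if (!("notes" %in% names(x))) x$notes <- ""
  x[, c("id", "left", "right", "reversible", "direction_evidence", "notes")]
}

#' Build a single reaction row
#'
#' Sides can be given as a character vector of metabolite ids (all
#' coefficients 1) or a named numeric vector of positive coefficients.
#' Left and right must be non-empty and a metabolite id may appear at most
#' once per side.
#'
#' @param id Unique reaction identifier.
#' @param left,right Substrate and product sides.
#' @param reversible Logical; reversible reactions act in both directions.
#' @param direction_evidence How the direction was assigned:
#'   `"metacyc_pathway"`, `"topological"` or `"unassigned"`.
#' @param notes Free text.
#' @return A one-row reaction tibble.
#' @export
reaction <- function(id, left, right, reversible = FALSE,
                     direction_evidence = "unassigned", notes = "") {
  left <- as_side(left, id, "left")
  right <- as_side(right, id, "right")
  direction_evidence <- match.arg(direction_evidence,
                                  c("unassigned", "metacyc_pathway", "topological"))
  tibble::tibble(
    id = as.character(id), left = list(left), right = list(right),
    reversible = isTRUE(reversible),
    direction_evidence = direction_evidence, notes = notes
  )
}

as_side <- function(x, rid, which) {
  if (is.character(x)) {
    x <- stats::setNames(rep(1, length(x)), x)
  }
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reaction ", rid, ": ", which, " side must be ids or a named numeric vector")
  }
  if (length(x) == 0) stop("reaction ", rid, ": empty ", which, " side")
  if (any(x <= 0)) stop("reaction ", rid, ": non-positive coefficient on ", which)
  if (anyDuplicated(names(x))) {
    stop("reaction ", rid, ": metabolite repeated on ", which, " side")
  }
  x[order(names(x))]
}

#' Combine reaction rows
#' @param ... One-row reaction tibbles from [reaction()], or reaction tibbles.
#' @return A reaction tibble.
#' @export
bind_reactions <- function(...) dplyr::bind_rows(...)

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (",
      sum(x$reactions$reversible), " reversible)\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Validate a metabolic network
#'
#' Checks the structural invariants of the data model and returns violations
#' as data, not errors: unique non-empty ids, non-empty reaction sides,
#' positive coefficients, and every metabolite referenced by a reaction
#' present in the metabolite table. The network is never modified.
#'
#' @param network A [metabolic_network()].
#' @return A character vector of human-readable violations; empty when the
#'   network is well-formed.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  v <- character()
  mets <- network$metabolites
  rxns <- network$reactions
  if (any(!nzchar(mets$id))) v <- c(v, "metabolite with empty id")
  dup <- unique(mets$id[duplicated(mets$id)])
  if (length(dup)) v <- c(v, paste0("duplicate metabolite id: ", dup))
  dup <- unique(rxns$id[duplicated(rxns$id)])
  if (length(dup)) v <- c(v, paste0("duplicate reaction id: ", dup))
  for (i in seq_len(nrow(rxns))) {
    rid <- rxns$id[i]
    for (side in c("left", "right")) {
      s <- rxns[[side]][[i]]
      if (length(s) == 0) {
        v <- c(v, paste0("reaction ", rid, ": empty ", side, " side"))
        next
      }
      if (any(s <= 0)) {
        v <- c(v, paste0("reaction ", rid, ": non-positive coefficient on ", side))
      }
      if (anyDuplicated(names(s))) {
        v <- c(v, paste0("reaction ", rid, ": repeated metabolite on ", side))
      }
      unknown <- setdiff(names(s), mets$id)
      if (length(unknown)) {
        v <- c(v, paste0("reaction ", rid, ": unknown metabolite ",
                         paste(unknown, collapse = ", ")))
      }
    }
  }
  v
}

#' Metabolite occurrences of a network
#'
#' One row per (reaction, side, metabolite) occurrence; the currency of the
#' filtering conservation invariant (occurrences kept + occurrences removed =
#' occurrences before).
#'
#' @param network A [metabolic_network()].
#' @return A tibble with columns `reaction_id`, `side`, `metabolite_id`,
#'   `coefficient`.
#' @export
occurrences <- function(network) {
  rxns <- network$reactions
  if (nrow(rxns) == 0) {
    return(tibble::tibble(reaction_id = character(), side = character(),
                          metabolite_id = character(), coefficient = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    purrr::map_dfr(c("left", "right"), function(side) {
      s <- rxns[[side]][[i]]
      tibble::tibble(reaction_id = rxns$id[i], side = side,
                     metabolite_id = names(s), coefficient = unname(s))
    })
  })
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a metabolic network
#' @param x A [metabolic_network()].
#' @param ... Unused.
#' @return A one-row tibble with metabolite, reaction and reversible-reaction
#'   counts.
#' @method glance metabolic_network
#' @export
glance.metabolic_network <- function(x, ...) {
  tibble::tibble(
    n_metabolites = nrow(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_reversible = sum(x$reactions$reversible)
  )
}

#' Reaction table of a network in long form
#' @param x A [metabolic_network()].
#' @param ... Unused.
#' @return The occurrence tibble of [occurrences()] joined with reversibility.
#' @method tidy metabolic_network
#' @export
tidy.metabolic_network <- function(x, ...) {
  dplyr::left_join(
    occurrences(x),
    dplyr::select(x$reactions, reaction_id = "id", "reversible"),
    by = "reaction_id"
  )
}

# canonical comparable form: ids, sorted sides, reversibility
network_signature <- function(network) {
  rxns <- network$reactions
  list(
    metabolites = sort(network$metabolites$id),
    reactions = if (nrow(rxns) == 0) list() else
      stats::setNames(lapply(seq_len(nrow(rxns)), function(i) {
        list(left = rxns$left[[i]], right = rxns$right[[i]],
             reversible = rxns$reversible[i])
      }), rxns$id)[order(rxns$id)]
  )
}

#' Test two networks for structural equality
#'
#' Compares metabolite id sets and, per reaction id, sides (ids and
#' coefficients) and reversibility. Display names, notes and provenance are
#' ignored.
#'
#' @param a,b Networks.
#' @return `TRUE` or `FALSE`.
#' @export
network_equal <- function(a, b) {
  identical(network_signature(a), network_signature(b))
}
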