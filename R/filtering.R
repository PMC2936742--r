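#' Side-compound transformation rules
#'
#' A rule describes one classical cofactor transformation (e.g. ATP -> ADP).
#' When all `trigger_left` metabolites occur on one side of a reaction and
#' all `trigger_right` metabolites on the other (in either orientation), the
#' `removed_left` / `removed_right` metabolites (supersets of the triggers,
#' allowing subproducts) are deleted from their respective sides. Partial
#' trigger matches do nothing.
#'
#' @param rule_id Identifier.
#' @param trigger_left,trigger_right Non-empty character vectors of
#'   metabolite ids.
#' @param removed_left,removed_right Character vectors; default to the
#'   triggers. Must contain their triggers.
#' @return A one-row rule tibble with list columns.
#' @export
side_compound_rule <- function(rule_id, trigger_left, trigger_right,
                               removed_left = trigger_left,
                               removed_right = trigger_right) {
  if (!length(trigger_left) || !length(trigger_right)) {
    stop("rule ", rule_id, ": empty trigger set")
  }
  if (!all(trigger_left %in% removed_left) ||
      !all(trigger_right %in% removed_right)) {
    stop("rule ", rule_id, ": removed sets must contain their triggers")
  }
  tibble::tibble(
    rule_id = as.character(rule_id),
    trigger_left = list(trigger_left), trigger_right = list(trigger_right),
    removed_left = list(removed_left), removed_right = list(removed_right)
  )
}

#' Read a side-compound rule table from CSV
#'
#' Columns: `rule_id`, `trigger_left`, `trigger_right`, `removed_left`,
#' `removed_right`; the four set columns are semicolon-separated id lists
#' (removed columns may be empty, defaulting to the triggers).
#'
#' @param path CSV file path.
#' @return A rule tibble.
#' @export
read_side_compound_rules <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  split_ids <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
  }
  purrr::map_dfr(seq_len(nrow(raw)), function(i) {
    tl <- split_ids(raw$trigger_left[i])
    tr <- split_ids(raw$trigger_right[i])
    rl <- split_ids(raw$removed_left[i])
    rr <- split_ids(raw$removed_right[i])
    side_compound_rule(raw$rule_id[i], tl, tr,
                       if (length(rl)) rl else tl,
                       if (length(rr)) rr else tr)
  })
}

#' Starter side-compound rule table
#'
#' The 24 classical cofactor transformations shipped with the package
#' (`inst/extdata/side_compound_rules.csv`): ATP/ADP, NAD/NADH and kindred
#' currency couples. This is a synthetic starter set using MetaCyc-style
#' ids; the rule file is configuration and real analyses should supply a
#' table curated for their networks' id space.
#'
#' @return A rule tibble.
#' @export
default_side_compound_rules <- function() {
  read_side_compound_rules(
    system.file("extdata", "side_compound_rules.csv", package = "seedscope",
                mustWork = TRUE)
  )
}

#' Default inorganic compound list
#'
#' The nine inorganic compounds removed from every reaction when reducing a
#' network to carbon metabolism: water, proton, phosphate, diphosphate,
#' ammonia, hydrogen peroxide, sulfite, sulfate and oxygen (MetaCyc-style
#' ids). Bicarbonate is deliberately absent: it carries carbon.
#'
#' @return A character vector of metabolite ids.
#' @export
inorganic_compounds <- function() {
  c("WATER", "PROTON", "Pi", "PPI", "AMMONIA",
    "HYDROGEN-PEROXIDE", "SO3", "SULFATE", "OXYGEN-MOLECULE")
}

empty_removal_log <- function() {
  tibble::tibble(entity_id = character(), kind = character(),
                 reason = character(), rule_id = character(),
                 reaction_id = character(), side = character())
}

log_occurrence <- function(met, reason, rule_id, reaction_id, side) {
  tibble::tibble(entity_id = met, kind = "metabolite-occurrence",
                 reason = reason, rule_id = rule_id,
                 reaction_id = reaction_id, side = side)
}

filter_result <- function(network, log) {
  structure(list(network = network, log = log), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", nrow(x$log), " removal log entries\n", sep = "")
  print(x$network)
  invisible(x)
}

#' Remove side compounds by transformation rules
#'
#' For each reaction and each rule, if the rule's transformation is present
#' (all left triggers on one side, all right triggers on the other, in
#' either orientation), the corresponding side compounds are removed from
#' the reaction. The input network is never modified; one log entry is
#' written per deleted occurrence. Applying the same rule set twice is a
#' no-op the second time (the triggers are gone).
#'
#' @param network A [metabolic_network()].
#' @param rules A rule tibble ([side_compound_rule()],
#'   [default_side_compound_rules()]).
#' @return A `filter_result`: `$network` (filtered copy) and `$log`
#'   (removal log tibble).
#' @export
apply_side_compound_rules <- function(network, rules = default_side_compound_rules()) {
  rxns <- network$reactions
  logs <- list(empty_removal_log())
  for (i in seq_len(nrow(rxns))) {
    left <- rxns$left[[i]]
    right <- rxns$right[[i]]
    for (k in seq_len(nrow(rules))) {
      tl <- rules$trigger_left[[k]]; tr <- rules$trigger_right[[k]]
      rl <- rules$removed_left[[k]]; rr <- rules$removed_right[[k]]
      hit_fwd <- all(tl %in% names(left)) && all(tr %in% names(right))
      hit_rev <- all(tl %in% names(right)) && all(tr %in% names(left))
      if (hit_fwd) {
        drop_l <- intersect(names(left), rl); drop_r <- intersect(names(right), rr)
      } else if (hit_rev) {
        drop_l <- intersect(names(left), rr); drop_r <- intersect(names(right), rl)
      } else next
      if (length(drop_l)) {
        logs[[length(logs) + 1L]] <- log_occurrence(
          drop_l, "side-compound", rules$rule_id[k], rxns$id[i], "left")
        left <- left[setdiff(names(left), drop_l)]
      }
      if (length(drop_r)) {
        logs[[length(logs) + 1L]] <- log_occurrence(
          drop_r, "side-compound", rules$rule_id[k], rxns$id[i], "right")
        right <- right[setdiff(names(right), drop_r)]
      }
    }
    rxns$left[[i]] <- left
    rxns$right[[i]] <- right
  }
  out <- network
  out$reactions <- rxns
  filter_result(out, dplyr::bind_rows(logs))
}

#' Remove inorganic compounds from every reaction
#'
#' Deletes every occurrence of the listed metabolites from every reaction
#' side and drops listed metabolites that end up participating in no
#' reaction from the metabolite table.
#'
#' @param network A [metabolic_network()].
#' @param inorganic_ids Metabolite ids to remove; defaults to
#'   [inorganic_compounds()].
#' @return A `filter_result`.
#' @export
remove_inorganics <- function(network, inorganic_ids = inorganic_compounds()) {
  rxns <- network$reactions
  logs <- list(empty_removal_log())
  for (i in seq_len(nrow(rxns))) {
    for (side in c("left", "right")) {
      s <- rxns[[side]][[i]]
      drop <- intersect(names(s), inorganic_ids)
      if (length(drop)) {
        logs[[length(logs) + 1L]] <- log_occurrence(
          drop, "inorganic", NA_character_, rxns$id[i], side)
        rxns[[side]][[i]] <- s[setdiff(names(s), drop)]
      }
    }
  }
  out <- network
  out$reactions <- rxns
  used <- unique(unlist(lapply(c(rxns$left, rxns$right), names)))
  orphaned <- setdiff(intersect(network$metabolites$id, inorganic_ids), used)
  if (length(orphaned)) {
    out$metabolites <- dplyr::filter(out$metabolites, !(.data$id %in% orphaned))
  }
  filter_result(out, dplyr::bind_rows(logs))
}

#' Drop reactions that no longer transfer carbon
#'
#' After side-compound and inorganic filtering, a reaction whose left or
#' right side has become empty cannot represent a transfer of carbon atoms
#' between its sides; such reactions are removed and logged with reason code
#' `NC`.
#'
#' @param network A [metabolic_network()] (already filtered).
#' @return A `filter_result`.
#' @export
drop_carbonless_reactions <- function(network) {
  rxns <- network$reactions
  empty <- vapply(seq_len(nrow(rxns)), function(i) {
    length(rxns$left[[i]]) == 0 || length(rxns$right[[i]]) == 0
  }, logical(1))
  log <- if (any(empty)) {
    tibble::tibble(entity_id = rxns$id[empty], kind = "reaction",
                   reason = "NC", rule_id = NA_character_,
                   reaction_id = rxns$id[empty], side = NA_character_)
  } else empty_removal_log()
  out <- network
  out$reactions <- rxns[!empty, ]
  filter_result(out, log)
}

#' Full carbon-core filtering pass
#'
#' Fixed pass order: side-compound rules, then inorganic removal, then
#' carbonless-reaction elimination, then (optionally) manual per-reaction
#' overrides. The order is recorded in the combined log's `reason` codes so
#' deviations are auditable.
#'
#' @param network A [metabolic_network()].
#' @param rules Side-compound rules; `NULL` skips the pass.
#' @param inorganic_ids Inorganic id list; `NULL` skips the pass.
#' @param overrides Optional tibble of manual corrections with columns
#'   `reaction_id`, `metabolite_id`, `side` (`"left"`/`"right"`), `action`
#'   (`"remove"` deletes the occurrence; `"keep"` restores it from the
#'   original network with its original coefficient).
#' @return A `filter_result` whose log concatenates all passes.
#' @export
filter_network <- function(network, rules = default_side_compound_rules(),
                           inorganic_ids = inorganic_compounds(),
                           overrides = NULL) {
  log <- empty_removal_log()
  cur <- network
  if (!is.null(rules) && nrow(rules)) {
    st <- apply_side_compound_rules(cur, rules)
    cur <- st$network; log <- dplyr::bind_rows(log, st$log)
  }
  if (!is.null(inorganic_ids) && length(inorganic_ids)) {
    st <- remove_inorganics(cur, inorganic_ids)
    cur <- st$network; log <- dplyr::bind_rows(log, st$log)
  }
  if (!is.null(overrides) && nrow(overrides)) {
    st <- apply_manual_overrides(cur, network, overrides)
    cur <- st$network; log <- dplyr::bind_rows(log, st$log)
  }
  st <- drop_carbonless_reactions(cur)
  cur <- st$network; log <- dplyr::bind_rows(log, st$log)
  # metabolites whose occurrences were all filtered away would otherwise
  # linger as isolated nodes and surface as spurious seeds downstream
  used <- unique(unlist(lapply(c(cur$reactions$left, cur$reactions$right), names)))
  touched <- unique(log$entity_id[log$kind == "metabolite-occurrence"])
  orphaned <- setdiff(intersect(cur$metabolites$id, touched), used)
  if (length(orphaned)) {
    cur$metabolites <- dplyr::filter(cur$metabolites, !(.data$id %in% orphaned))
  }
  filter_result(cur, log)
}

apply_manual_overrides <- function(network, original, overrides) {
  rxns <- network$reactions
  logs <- list(empty_removal_log())
  for (i in seq_len(nrow(overrides))) {
    rid <- overrides$reaction_id[i]
    mid <- overrides$metabolite_id[i]
    side <- overrides$side[i]
    j <- match(rid, rxns$id)
    if (is.na(j)) next
    s <- rxns[[side]][[j]]
    if (identical(overrides$action[i], "remove") && mid %in% names(s)) {
      rxns[[side]][[j]] <- s[setdiff(names(s), mid)]
      logs[[length(logs) + 1L]] <- log_occurrence(mid, "manual-remove",
                                                  NA_character_, rid, side)
    } else if (identical(overrides$action[i], "keep") && !(mid %in% names(s))) {
      k <- match(rid, original$reactions$id)
      coef <- original$reactions[[side]][[k]][mid]
      if (!is.na(coef)) {
        s <- c(s, stats::setNames(unname(coef), mid))
        rxns[[side]][[j]] <- s[order(names(s))]
      }
    }
  }
  out <- network
  out$reactions <- rxns
  filter_result(out, dplyr::bind_rows(logs))
}

#' Flag reactions disconnected from the rest of the network
#'
#' A reaction is flagged when all of its substrates are produced by no other
#' reaction and all of its products are consumed by no other reaction (for
#' reversible reactions, both orientations of every reaction are
#' considered). Such reactions are candidates for manual curation; nothing
#' is removed.
#'
#' @param network A [metabolic_network()].
#' @return A character vector of reaction ids.
#' @export
detect_disconnected_reactions <- function(network) {
  rxns <- network$reactions
  n <- nrow(rxns)
  if (n == 0) return(character())
  prod_by <- vector("list", n)
  cons_by <- vector("list", n)
  for (i in seq_len(n)) {
    l <- names(rxns$left[[i]]); r <- names(rxns$right[[i]])
    if (rxns$reversible[i]) {
      prod_by[[i]] <- union(l, r); cons_by[[i]] <- union(l, r)
    } else {
      prod_by[[i]] <- r; cons_by[[i]] <- l
    }
  }
  flagged <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    produced_elsewhere <- unique(unlist(prod_by[others]))
    consumed_elsewhere <- unique(unlist(cons_by[others]))
    orient_dead <- function(sub, pro) {
      !any(sub %in% produced_elsewhere) && !any(pro %in% consumed_elsewhere)
    }
    l <- names(rxns$left[[i]]); r <- names(rxns$right[[i]])
    if (rxns$reversible[i]) orient_dead(l, r) && orient_dead(r, l)
    else orient_dead(l, r)
  }, logical(1))
  rxns$id[flagged]
}

#' Split a reaction on a generic compound
#'
#' Replaces one reaction involving a generic metabolite (e.g. "lysine or
#' meso-diaminopimelate") with one specific reaction per substitution. New
#' ids are suffixed deterministically: `BIS`, `TER`, `QUATER`, then the
#' substitution's ordinal number.
#'
#' @param rxn A one-row reaction tibble.
#' @param substitutions A list of `c(generic_id, specific_id)` pairs.
#' @return A reaction tibble with one row per substitution (possibly empty).
#' @export
split_generic_reaction <- function(rxn, substitutions) {
  stopifnot(nrow(rxn) == 1)
  suffixes <- c("BIS", "TER", "QUATER")
  out <- list()
  for (i in seq_along(substitutions)) {
    pair <- substitutions[[i]]
    generic <- pair[[1]]; specific <- pair[[2]]
    left <- rxn$left[[1]]; right <- rxn$right[[1]]
    if (!(generic %in% c(names(left), names(right)))) {
      stop("generic metabolite ", generic, " absent from reaction ", rxn$id)
    }
    rename_side <- function(s) {
      names(s)[names(s) == generic] <- specific
      s[order(names(s))]
    }
    suffix <- if (i <= length(suffixes)) suffixes[i] else as.character(i + 1)
    out[[i]] <- tibble::tibble(
      id = paste0(rxn$id, suffix),
      left = list(rename_side(left)), right = list(rename_side(right)),
      reversible = rxn$reversible, direction_evidence = rxn$direction_evidence,
      notes = rxn$notes
    )
  }
  if (length(out)) dplyr::bind_rows(out) else as_reaction_tbl(NULL)
}

#' Write a removal log as TSV
#' @param log A removal log tibble (from a `filter_result`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(log, path) {
  readr::write_tsv(log, path)
  invisible(path)
}
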