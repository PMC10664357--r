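#' Majority-vote consensus of a model ensemble
#'
#' Collapses alternative reconstructions of one organism into a single
#' model: a reaction is included iff it appears in at least `threshold`
#' of the members (the "at least half" rule is read inclusively, so with
#' an even ensemble size N a reaction in exactly N/2 members is included).
#' Bounds of an included reaction are merged to the widest interval over
#' the members containing it; metabolites are the union over included
#' reactions; the biomass reaction is always included.
#'
#' @param models list of `metabolic_model` objects sharing a namespace.
#' @param threshold inclusion fraction in (0, 1]; default 0.5.
#' @param match `"id"` (default) or `"signature"` reaction identity.
#' @return the consensus `metabolic_model`.
#' @export
consensus <- function(models, threshold = 0.5, match = c("id", "signature")) {
  match <- match.arg(match)
  stopifnot(length(models) >= 1, threshold > 0, threshold <= 1)
  n <- length(models)
  key_of <- function(m) {
    if (match == "id") m$reactions$id
    else vapply(m$reactions$stoichiometry, canonical_signature, "")
  }
  keys <- lapply(models, key_of)
  counts <- table(unlist(lapply(keys, unique)))
  included <- names(counts)[counts / n >= threshold]

  ref <- models[[1]]
  # conflict check + collect per-key representative rows and merged bounds
  rows <- list(); met_rows <- list()
  seen_sig <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    k <- keys[[i]]
    for (j in seq_along(k)) {
      key <- k[j]
      keep <- key %in% included ||
        (i == 1L && m$reactions$id[j] == ref$biomass_reaction)
      if (!keep) next
      sig <- canonical_signature(m$reactions$stoichiometry[[j]])
      if (is.null(rows[[key]])) {
        rows[[key]] <- m$reactions[j, , drop = FALSE]
        seen_sig[[key]] <- sig
      } else {
        if (match == "id" && !identical(sig, seen_sig[[key]]))
          stop("conflicting stoichiometry across ensemble for reaction: ",
               key)
        rows[[key]]$lower_bound <-
          min(rows[[key]]$lower_bound, m$reactions$lower_bound[j])
        rows[[key]]$upper_bound <-
          max(rows[[key]]$upper_bound, m$reactions$upper_bound[j])
      }
    }
    met_rows[[i]] <- m$metabolites
  }
  # preserve the first model's reaction order where possible
  ord <- unique(c(intersect(keys[[1]], names(rows)),
                  setdiff(names(rows), keys[[1]])))
  rxns <- do.call(rbind, rows[ord])
  rownames(rxns) <- NULL
  if (anyDuplicated(rxns$id))
    stop("signature-matched consensus produced duplicate reaction ids")

  mets <- do.call(rbind, met_rows)
  mets <- mets[!duplicated(mets$id), , drop = FALSE]
  used <- unique(unlist(lapply(rxns$stoichiometry, names)))
  mets <- mets[mets$id %in% used, , drop = FALSE]
  rownames(mets) <- NULL
  comps <- ref$compartments
  for (m in models) {
    new <- setdiff(names(m$compartments), names(comps))
    comps <- c(comps, m$compartments[new])
  }
  metabolic_model(mets, rxns, comps, ref$biomass_reaction,
                  ref$objective_sense)
}
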