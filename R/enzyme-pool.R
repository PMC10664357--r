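#' Read an enzyme-parameter table
#'
#' Delimited text with header columns `reaction_id`, `kcat_fwd`,
#' `kcat_rev`, `kcat_unit`, `mw_g_per_mmol`, `draws_from_pool`. Turnover
#' numbers are stored in 1/h; rows with `kcat_unit` of `"1/s"` (or `"s-1"`)
#' are converted by a factor 3600. Duplicate rows for one reaction are
#' collapsed to their median parameters.
#'
#' @param path file path.
#' @return data.frame of enzyme entries (kcat in 1/h).
#' @export
read_enzyme_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "kcat_fwd", "mw_g_per_mmol", "draws_from_pool")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("enzyme table lacking column(s): ", paste(missing, collapse = ", "))
  if (is.null(tab$kcat_rev)) tab$kcat_rev <- tab$kcat_fwd
  if (is.null(tab$kcat_unit)) tab$kcat_unit <- "1/h"
  per_s <- tab$kcat_unit %in% c("1/s", "s-1", "s^-1", "/s")
  tab$kcat_fwd[per_s] <- tab$kcat_fwd[per_s] * 3600
  tab$kcat_rev[per_s] <- tab$kcat_rev[per_s] * 3600
  tab$kcat_unit <- "1/h"
  tab$draws_from_pool <- as.logical(tab$draws_from_pool)
  if (anyDuplicated(tab$reaction_id)) {
    tab <- do.call(rbind, lapply(split(tab, tab$reaction_id), function(d) {
      d$kcat_fwd[1] <- stats::median(d$kcat_fwd)
      d$kcat_rev[1] <- stats::median(d$kcat_rev)
      d$mw_g_per_mmol[1] <- stats::median(d$mw_g_per_mmol)
      d[1, , drop = FALSE]
    }))
    rownames(tab) <- NULL
  }
  tab
}

#' Write an enzyme-parameter table
#'
#' @param entries data.frame of enzyme entries.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enzyme_table <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Augment a model with a finite enzymatic protein pool
#'
#' sMOMENT-style augmentation: a protein-pool pseudo-metabolite is supplied
#' by a single delivery reaction bounded by `p_tot` (g protein/gDW). Every
#' reaction flagged `draws_from_pool` consumes
#' `mw / (kcat * saturation)` grams of pool per unit flux in each catalyzed
#' direction; reversible pooled reactions are split into irreversible
#' forward and backward halves (forward keeps the original id and
#' `[max(0, lb), ub]`; the backward copy gets the suffix `_REV` and
#' `[0, -lb]`) so each direction carries its own cost. Reactions without a
#' table entry, or flagged `draws_from_pool = FALSE`, carry no protein cost
#' (mirroring reactions without an enzyme annotation); with
#' `strict = TRUE` a missing entry for a candidate enzymatic reaction is an
#' error instead of a warning.
#'
#' @param model a `metabolic_model`.
#' @param entries enzyme table (see [read_enzyme_table()]); kcat in 1/h.
#' @param p_tot total protein pool, g/gDW.
#' @param saturation enzyme saturation factor in (0, 1]; the package
#'   convention is full saturation (1).
#' @param strict error on pooled reactions lacking parameters.
#' @return a `protein_pool_model`: list with the augmented `base` model,
#'   `pool_metabolite_id`, `pool_exchange_id`, `p_tot`, `saturation`, and
#'   `split_map` (original id -> c(forward, backward)).
#' @export
augment_with_pool <- function(model, entries, p_tot, saturation = 1,
                              strict = FALSE) {
  stopifnot(p_tot > 0, saturation > 0, saturation <= 1)
  unknown <- setdiff(entries$reaction_id, model$reactions$id)
  if (length(unknown))
    stop("enzyme entries reference unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  pooled <- entries[entries$draws_from_pool, , drop = FALSE]
  bad <- pooled$kcat_fwd <= 0 | pooled$mw_g_per_mmol <= 0 |
    (!is.na(pooled$kcat_rev) & pooled$kcat_rev <= 0)
  if (any(bad))
    stop("non-positive kcat or molecular weight for pooled reaction(s): ",
         paste(pooled$reaction_id[bad], collapse = ", "))
  candidates <- setdiff(model$reactions$id,
                        c(exchange_reactions(model), model$biomass_reaction))
  uncovered <- setdiff(candidates, entries$reaction_id)
  if (length(uncovered)) {
    msg <- paste("reactions without enzyme parameters carry no protein cost:",
                 paste(uncovered, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }

  pool_met <- "prot_pool_c"
  pool_ex <- "PROT_POOL_delivery"
  mets <- model$metabolites
  mets <- rbind(mets, data.frame(id = pool_met, name = "protein pool",
                                 compartment = "c", formula = NA_character_,
                                 charge = NA_integer_,
                                 stringsAsFactors = FALSE))
  rxns <- model$reactions
  split_map <- list()
  extra <- list()
  for (i in seq_len(nrow(pooled))) {
    id <- pooled$reaction_id[i]
    j <- match(id, rxns$id)
    mw <- pooled$mw_g_per_mmol[i]
    kf <- pooled$kcat_fwd[i]
    kr <- pooled$kcat_rev[i]
    if (is.na(kr)) kr <- kf
    cost_f <- mw / (kf * saturation)
    st <- rxns$stoichiometry[[j]]
    lbj <- rxns$lower_bound[j]; ubj <- rxns$upper_bound[j]
    if (lbj < 0) {
      rev_id <- paste0(id, "_REV")
      extra[[length(extra) + 1L]] <- list(
        id = rev_id, name = paste0(rxns$name[j], " (backward)"),
        st = c(-st, stats::setNames(-mw / (kr * saturation), pool_met)),
        lb = 0, ub = -lbj, gene = rxns$gene_association[j])
      rxns$lower_bound[j] <- max(0, lbj)
      split_map[[id]] <- c(forward = id, backward = rev_id)
    }
    rxns$stoichiometry[[j]] <- c(st, stats::setNames(-cost_f, pool_met))
  }
  if (length(extra)) {
    add_df <- data.frame(
      id = vapply(extra, `[[`, "", "id"),
      name = vapply(extra, `[[`, "", "name"),
      lower_bound = vapply(extra, `[[`, 0, "lb"),
      upper_bound = vapply(extra, `[[`, 0, "ub"),
      gene_association = vapply(extra, `[[`, "", "gene"),
      stringsAsFactors = FALSE)
    add_df$stoichiometry <- lapply(extra, `[[`, "st")
    rxns <- rbind(rxns, add_df[names(rxns)])
  }
  delivery <- data.frame(id = pool_ex, name = "protein pool delivery",
                         lower_bound = 0, upper_bound = p_tot,
                         gene_association = NA_character_,
                         stringsAsFactors = FALSE)
  delivery$stoichiometry <- list(stats::setNames(1, pool_met))
  rxns <- rbind(rxns, delivery[names(rxns)])

  base <- metabolic_model(mets, rxns, model$compartments,
                          model$biomass_reaction, model$objective_sense)
  structure(list(base = base, pool_metabolite_id = pool_met,
                 pool_exchange_id = pool_ex, p_tot = p_tot,
                 saturation = saturation, split_map = split_map),
            class = "protein_pool_model")
}

#' @export
print.protein_pool_model <- function(x, ...) {
  cat("<protein_pool_model> p_tot =", x$p_tot, "g/gDW; saturation =",
      x$saturation, ";", length(x$split_map), "split reactions\n")
  invisible(x)
}

#' Set the protein pool level
#'
#' Updates the pool delivery upper bound; nothing else changes.
#'
#' @param pmodel a `protein_pool_model`.
#' @param level new pool level, g/gDW (may be `Inf` for the effectively
#'   unconstrained case).
#' @return modified copy of `pmodel`.
#' @export
set_pool_level <- function(pmodel, level) {
  stopifnot(inherits(pmodel, "protein_pool_model"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0)
    stop("pool level must be a positive number")
  lv <- if (is.finite(level)) level else 1e9
  pmodel$base <- set_bounds(pmodel$base, pmodel$pool_exchange_id,
                            upper = lv)
  pmodel$p_tot <- level
  pmodel
}

#' Protein pool equivalent under the full-saturation convention
#'
#' Converts a literature `(P_tot, sigma)` parameterization into the pool
#' level that reproduces it when the saturation factor is fixed at one:
#' `P_tot * sigma`.
#'
#' @param p_tot_literature literature pool size, g/gDW.
#' @param sigma literature saturation factor.
#' @return equivalent pool at full saturation, g/gDW.
#' @export
equivalent_pool <- function(p_tot_literature, sigma) {
  stopifnot(p_tot_literature > 0, sigma > 0)
  p_tot_literature * sigma
}

#' Protein usage of a flux solution
#'
#' Sum of `mw/(kcat * saturation) * v` over pooled reaction directions,
#' i.e. the pool delivery flux at the optimum.
#'
#' @param pmodel a `protein_pool_model`.
#' @param solution a `flux_solution` on `pmodel$base`.
#' @return grams of protein per gDW used.
#' @export
pool_usage <- function(pmodel, solution) {
  stopifnot(inherits(pmodel, "protein_pool_model"),
            !is.null(solution$fluxes))
  unname(solution$fluxes[pmodel$pool_exchange_id])
}
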