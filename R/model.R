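#' Compartmentalized metabolic model objects
#'
#' A `metabolic_model` is the package's container for a compartmentalized
#' stoichiometric network: a metabolite table, a reaction table with bounds
#' and stoichiometry, a compartment dictionary, and a designated biomass
#' reaction. Steady-state flux analysis treats the model as the linear system
#' `S v = 0` with `lb <= v <= ub`, where `S` has one row per (non-boundary)
#' metabolite and one column per reaction.
#'
#' Metabolites placed in the reserved `"b"` (boundary) compartment are
#' excluded from mass balance, following the usual exchange convention.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   and optionally `formula`, `charge`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, optionally `name`, `gene_association`, and a list column
#'   `stoichiometry` of named numeric vectors (negative = consumed).
#' @param compartments named character vector mapping compartment id to name.
#' @param biomass_reaction id of the biomass reaction.
#' @param objective_sense `"maximize"` or `"minimize"`.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, compartments,
                            biomass_reaction,
                            objective_sense = c("maximize", "minimize")) {
  objective_sense <- match.arg(objective_sense)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gene_association))
    reactions$gene_association <- NA_character_
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         compartments = compartments, biomass_reaction = biomass_reaction,
         objective_sense = objective_sense),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, bound ordering, that every stoichiometry key
#' resolves to a metabolite, that compartments exist, and that the biomass
#' reaction is present.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  known_comp <- c(names(model$compartments), "b")
  bad_comp <- setdiff(unique(mets$compartment), known_comp)
  if (length(bad_comp))
    stop("metabolite compartment not in compartment list: ",
         paste(bad_comp, collapse = ", "))
  if (any(rxns$lower_bound > rxns$upper_bound))
    stop("lower_bound > upper_bound for reaction: ",
         paste(rxns$id[rxns$lower_bound > rxns$upper_bound], collapse = ", "))
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    if (length(st) == 0L)
      stop("empty stoichiometry for reaction ", rxns$id[i])
    missing <- setdiff(names(st), mets$id)
    if (length(missing))
      stop("reaction ", rxns$id[i], " references unknown metabolite: ",
           paste(missing, collapse = ", "))
  }
  if (!model$biomass_reaction %in% rxns$id)
    stop("biomass reaction '", model$biomass_reaction, "' not in model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,",
      length(x$compartments), "compartments\n")
  cat("  biomass:", x$biomass_reaction,
      "| reversible:", sum(is_reversible(x)), "\n")
  invisible(x)
}

#' Stoichiometric matrix
#'
#' Sparse matrix `S` with one row per non-boundary metabolite and one column
#' per reaction.
#'
#' @param model a `metabolic_model`.
#' @return a `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites
  keep <- mets$id[mets$compartment != "b"]
  met_index <- stats::setNames(seq_along(keep), keep)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    st <- st[names(st) %in% keep]
    if (length(st)) {
      ii <- c(ii, met_index[names(st)])
      jj <- c(jj, rep.int(j, length(st)))
      xx <- c(xx, unname(st))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(keep), nrow(model$reactions)),
                       dimnames = list(keep, model$reactions$id))
}

#' Reversibility of reactions
#'
#' A reaction is counted as reversible iff `lower_bound < 0 < upper_bound`.
#'
#' @param model a `metabolic_model`.
#' @return named logical vector over reaction ids.
#' @export
is_reversible <- function(model) {
  stats::setNames(model$reactions$lower_bound < 0 &
                    model$reactions$upper_bound > 0,
                  model$reactions$id)
}

#' Exchange reactions
#'
#' Reactions touching exactly one non-boundary metabolite (the usual
#' single-species exchange convention).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  boundary <- model$metabolites$id[model$metabolites$compartment == "b"]
  sel <- vapply(model$reactions$stoichiometry, function(st) {
    sum(!(names(st) %in% boundary)) == 1L
  }, logical(1))
  model$reactions$id[sel]
}

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id: ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Set flux bounds on reactions
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids.
#' @param lower,upper new bounds (recycled); `NULL` leaves a side unchanged.
#' @return modified copy of the model.
#' @export
set_bounds <- function(model, ids, lower = NULL, upper = NULL) {
  idx <- rxn_index(model, ids)
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- upper
  model
}

#' Knock out reactions
#'
#' Returns a copy of the model with both bounds of the listed reactions set
#' to zero; the input model is untouched.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids ids to disable.
#' @return modified copy of the model.
#' @export
knockout <- function(model, reaction_ids) {
  set_bounds(model, reaction_ids, lower = 0, upper = 0)
}

canonical_signature <- function(st) {
  st <- st[abs(st) > 0]
  o <- order(names(st))
  st <- st[o]
  # direction-normalized: flip so the lexicographically first metabolite
  # carries a negative coefficient
  if (st[[1]] > 0) st <- -st
  paste(names(st), format(st, digits = 12, trim = TRUE),
        sep = ":", collapse = ";")
}

#' Reactions of one model absent from another
#'
#' With `match = "id"` reaction ids are compared verbatim (the default;
#' appropriate when both models share a universal-model namespace). With
#' `match = "signature"` canonicalized stoichiometries are compared instead:
#' compartment-qualified metabolite:coefficient pairs, sorted, with the
#' direction normalized.
#'
#' @param model_a,model_b `metabolic_model` objects.
#' @param match `"id"` or `"signature"`.
#' @return character vector of reaction ids of `model_a` with no counterpart
#'   in `model_b`, in `model_a`'s reaction order.
#' @export
reaction_set_difference <- function(model_a, model_b,
                                    match = c("id", "signature")) {
  match <- match.arg(match)
  if (match == "id") {
    setdiff_keep <- !(model_a$reactions$id %in% model_b$reactions$id)
  } else {
    sig_a <- vapply(model_a$reactions$stoichiometry, canonical_signature, "")
    sig_b <- vapply(model_b$reactions$stoichiometry, canonical_signature, "")
    setdiff_keep <- !(sig_a %in% sig_b)
  }
  model_a$reactions$id[setdiff_keep]
}

#' Transplant a reaction from one model into another
#'
#' Copies the reaction (and any metabolites it uses that the target lacks,
#' keeping their source compartments) into a copy of the target model.
#'
#' @param source model containing the reaction.
#' @param target model to receive it.
#' @param reaction_id id of the reaction to copy.
#' @return modified copy of `target`.
#' @export
transplant_reaction <- function(source, target, reaction_id) {
  i <- rxn_index(source, reaction_id)
  rxn <- source$reactions[i, , drop = FALSE]
  if (reaction_id %in% target$reactions$id) {
    j <- rxn_index(target, reaction_id)
    same <- identical(
      canonical_signature(rxn$stoichiometry[[1]]),
      canonical_signature(target$reactions$stoichiometry[[j]]))
    if (!same)
      stop("reaction '", reaction_id,
           "' already exists in target with different stoichiometry")
    return(target)
  }
  need <- setdiff(names(rxn$stoichiometry[[1]]), target$metabolites$id)
  if (length(need)) {
    add <- source$metabolites[match(need, source$metabolites$id), ,
                              drop = FALSE]
    new_comp <- setdiff(add$compartment, c(names(target$compartments), "b"))
    if (length(new_comp)) {
      extra <- source$compartments[new_comp]
      target$compartments <- c(target$compartments, extra)
    }
    target$metabolites <- rbind(target$metabolites,
                                add[names(target$metabolites)])
  }
  target$reactions <- rbind(target$reactions, rxn[names(target$reactions)])
  validate_model(target)
  target
}
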