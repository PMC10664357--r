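#' Flux balance analysis
#'
#' Solves the LP `max/min v[objective]` subject to `S v = 0` and the model's
#' flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective_reaction reaction id to optimize; defaults to the
#'   model's biomass reaction.
#' @param sense `"max"` or `"min"`; defaults to the model's objective sense.
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, and `fluxes`
#'   (named vector over reaction ids; `NULL` unless optimal).
#' @export
fba <- function(model, objective_reaction = model$biomass_reaction,
                sense = NULL) {
  if (is.null(sense))
    sense <- if (model$objective_sense == "maximize") "max" else "min"
  sense <- match.arg(sense, c("max", "min"))
  idx <- rxn_index(model, objective_reaction)
  S <- stoichiometric_matrix(model)
  obj <- numeric(ncol(S)); obj[idx] <- 1
  sol <- solve_lp(obj, S, rep(0, nrow(S)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  maximize = (sense == "max"))
  flux_solution(sol, model)
}

flux_solution <- function(sol, model) {
  fluxes <- NULL
  if (sol$status == "optimal")
    fluxes <- stats::setNames(sol$x, model$reactions$id)
  structure(list(status = sol$status, objective_value = sol$objective,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution>", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Lexicographic objective specification
#'
#' An ordered list of optimization stages. Each stage optimizes one
#' reaction's flux; its optimum is then fixed (within a relative slack)
#' before the next stage is solved.
#'
#' @param stages list of `c(reaction_id, sense)` pairs or a two-column
#'   data.frame with columns `reaction` and `sense` (`"max"`/`"min"`).
#' @param fix_tolerance relative slack used when fixing stage optima.
#' @return a `lex_objective` object.
#' @export
lex_objective <- function(stages, fix_tolerance = 1e-6) {
  if (is.data.frame(stages)) {
    stages <- Map(function(r, s) c(r, s), stages$reaction, stages$sense)
  }
  stages <- lapply(stages, function(st) {
    st <- as.character(st)
    stopifnot(length(st) == 2L, st[2] %in% c("max", "min"))
    st
  })
  if (!length(stages)) stop("lexicographic objective needs at least one stage")
  structure(list(stages = stages, fix_tolerance = fix_tolerance),
            class = "lex_objective")
}

#' Lexicographic (multi-stage) flux balance analysis
#'
#' Solves the stages of `lex` in order. After each stage the optimized
#' reaction's flux is constrained to its optimum (within
#' `fix_tolerance * max(1, |optimum|)` relative slack) before the next stage
#' is solved. Later stages therefore cannot degrade earlier ones: this is
#' the tie-breaking rule used everywhere fluxes are reported, removing
#' alternate-optima nondeterminism.
#'
#' @param model a `metabolic_model`.
#' @param lex a `lex_objective`. Stage reactions missing from the model are
#'   skipped with a warning (species models differ in their exchanges).
#' @return a `flux_solution` carrying the final stage's solution, with
#'   `stage_optima` (named vector of each stage's optimum) attached. On any
#'   infeasible stage, `status` is `"infeasible"` and `failed_stage` names
#'   the stage.
#' @export
lexicographic_fba <- function(model, lex) {
  stopifnot(inherits(lex, "lex_objective"))
  present <- vapply(lex$stages, function(st) st[1] %in% model$reactions$id,
                    logical(1))
  if (!all(present)) {
    warning("skipping lexicographic stages for absent reactions: ",
            paste(vapply(lex$stages[!present], `[`, "", 1), collapse = ", "))
    lex$stages <- lex$stages[present]
    if (!length(lex$stages)) stop("no lexicographic stage reaction present")
  }
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  optima <- stats::setNames(numeric(length(lex$stages)),
                            vapply(lex$stages, `[`, "", 1))
  sol <- NULL
  for (k in seq_along(lex$stages)) {
    st <- lex$stages[[k]]
    idx <- rxn_index(model, st[1])
    obj <- numeric(ncol(S)); obj[idx] <- 1
    sol <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub,
                    maximize = (st[2] == "max"))
    if (sol$status != "optimal") {
      out <- structure(list(status = sol$status,
                            objective_value = NA_real_, fluxes = NULL,
                            failed_stage = k,
                            stage_optima = optima[seq_len(k - 1L)]),
                       class = "flux_solution")
      return(out)
    }
    opt <- sol$objective
    optima[k] <- opt
    slack <- lex$fix_tolerance * max(1, abs(opt))
    if (st[2] == "max") lb[idx] <- max(lb[idx], opt - slack)
    else ub[idx] <- min(ub[idx], opt + slack)
  }
  out <- flux_solution(sol, model)
  out$objective_value <- optima[[1]]
  out$stage_optima <- optima
  out
}

#' Default five-stage lexicographic ordering for batch simulations
#'
#' Maximize biomass; minimize glucose consumption (implemented as
#' maximization of the signed glucose exchange flux, whose upper bound is
#' zero in a batch medium, so the least-negative uptake wins); then maximize
#' excretion of ethanol, acetate, and glycerol, in that order.
#'
#' @param model a `metabolic_model` (supplies the biomass id).
#' @param glucose,ethanol,acetate,glycerol exchange reaction ids.
#' @param fix_tolerance relative slack when fixing stage optima.
#' @return a `lex_objective`.
#' @export
default_lex <- function(model, glucose = "EX_glc__D_e",
                        ethanol = "EX_etoh_e", acetate = "EX_ac_e",
                        glycerol = "EX_glyc_e", fix_tolerance = 1e-6) {
  lex_objective(list(c(model$biomass_reaction, "max"),
                     c(glucose, "max"),
                     c(ethanol, "max"),
                     c(acetate, "max"),
                     c(glycerol, "max")),
                fix_tolerance = fix_tolerance)
}
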