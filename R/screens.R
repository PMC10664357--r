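#' Apply the batch starting medium to a model
#'
#' Convenience wrapper fixing the model's environment to the state used for
#' initiating batch simulations: substrate uptake bounds at the initial
#' concentrations, fixed supplies, blocked reactions closed, products
#' secretion-only.
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()].
#' @param state a [culture_state()].
#' @return the model with medium bounds applied.
#' @export
screen_medium <- function(model, config = sim_config(),
                          state = culture_state()) {
  suppressWarnings(
    apply_environment(model, state, config$kinetics, config$supplies,
                      c(config$blocked_exports, config$blocked_internal),
                      config$tracked))
}

#' Cumulative knockout screen
#'
#' Iterates the candidate reactions in the given order, knocking each out
#' on top of all previous non-essential knockouts. A knockout that drops
#' the growth optimum below `essentiality_threshold` is marked essential
#' and reinserted before continuing. After every step the screen metric is
#' recorded: `"growth"` is the lexicographic stage-1 (plain FBA) optimum;
#' `"fermentation"` is the summed ethanol + acetate stage optima of the
#' full lexicographic solve on the starting medium (a deterministic
#' steady-state proxy for batch-endpoint fermentation; set
#' `dfba_endpoint = TRUE` to use the summed final concentrations of a full
#' batch simulation instead).
#'
#' @param model a `metabolic_model` (medium bounds are applied internally).
#' @param candidates reaction ids, screened in this order.
#' @param metric `"growth"` or `"fermentation"`.
#' @param config a [sim_config()] defining the medium (and the batch run in
#'   endpoint mode).
#' @param state initial [culture_state()] of the medium.
#' @param essentiality_threshold growth below this (1/h) marks a knockout
#'   essential.
#' @param dfba_endpoint use batch-endpoint concentrations for the
#'   fermentation metric.
#' @return a `knockout_screen`: list with `records` (one row per candidate:
#'   `reaction_id`, `essential`, `reinserted`, `growth`, `metric`),
#'   `baseline_growth`, `baseline_metric`, and `metric`.
#' @export
cumulative_knockout_screen <- function(model, candidates,
                                       metric = c("growth", "fermentation"),
                                       config = sim_config(),
                                       state = culture_state(),
                                       essentiality_threshold = 1e-9,
                                       dfba_endpoint = FALSE) {
  metric <- match.arg(metric)
  if (!length(candidates))
    return(structure(list(records = data.frame(), metric = metric),
                     class = "knockout_screen"))
  rxn_index(model, candidates)
  current <- screen_medium(model, config, state)
  lex <- default_lex(current)
  eval_metric <- function(m, growth) {
    if (metric == "growth") return(growth)
    if (dfba_endpoint) {
      res <- simulate_batch(m, state, config)
      fin <- res$trajectory[nrow(res$trajectory), ]
      return(fin$ethanol + fin$acetate)
    }
    sol <- lexicographic_fba(m, lex)
    if (sol$status != "optimal") return(NA_real_)
    sum(sol$stage_optima[c("EX_etoh_e", "EX_ac_e")])
  }
  g0 <- fba(current)
  if (g0$status != "optimal")
    stop("screen base model is ", g0$status, " on the given medium")
  baseline_growth <- g0$objective_value
  baseline_metric <- eval_metric(current, baseline_growth)

  rec <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    trial <- knockout(current, candidates[k])
    g <- fba(trial)
    growth <- if (g$status == "optimal") g$objective_value else 0
    essential <- growth < essentiality_threshold
    if (essential) {
      # reinserted: the cumulative model reverts to the previous step
      prev <- if (k > 1L) rec[[k - 1L]] else
        list(growth = baseline_growth, metric = baseline_metric)
      rec[[k]] <- list(reaction_id = candidates[k], essential = TRUE,
                       reinserted = TRUE, growth = prev$growth,
                       metric = prev$metric)
    } else {
      current <- trial
      rec[[k]] <- list(reaction_id = candidates[k], essential = FALSE,
                       reinserted = FALSE, growth = growth,
                       metric = eval_metric(current, growth))
    }
  }
  records <- do.call(rbind, lapply(rec, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  structure(list(records = records, baseline_growth = baseline_growth,
                 baseline_metric = baseline_metric, metric = metric),
            class = "knockout_screen")
}

#' @export
print.knockout_screen <- function(x, ...) {
  cat("<knockout_screen>", nrow(x$records), "candidates; metric =",
      x$metric, "; baseline =", format(x$baseline_metric, digits = 6), "\n")
  if (nrow(x$records)) {
    eff <- screen_effects(x)
    cat("  metric-altering:",
        if (length(eff)) paste(eff, collapse = ", ") else "(none)", "\n")
    cat("  essential:", sum(x$records$essential), "\n")
  }
  invisible(x)
}

#' Reactions whose cumulative knockout altered the screen metric
#'
#' A candidate is flagged when its (non-essential) knockout step changed
#' the recorded metric, relative to the preceding retained value, by more
#' than `rel_tol`. The default threshold depends on the metric: the growth
#' metric is a single LP optimum and uses a tight `1e-6`; the fermentation
#' metric accumulates the slack of four lexicographic stage fixings, so its
#' numerical noise floor is larger and `1e-3` is used.
#'
#' @param screen a `knockout_screen`.
#' @param rel_tol relative change threshold; `NULL` for the metric default.
#' @return character vector of flagged reaction ids.
#' @export
screen_effects <- function(screen, rel_tol = NULL) {
  stopifnot(inherits(screen, "knockout_screen"))
  if (is.null(rel_tol))
    rel_tol <- if (screen$metric == "growth") 1e-6 else 1e-3
  rec <- screen$records
  if (!nrow(rec)) return(character(0))
  prev <- screen$baseline_metric
  flagged <- character(0)
  for (k in seq_len(nrow(rec))) {
    if (!rec$essential[k]) {
      if (abs(rec$metric[k] - prev) > rel_tol * max(1, abs(prev)))
        flagged <- c(flagged, rec$reaction_id[k])
      prev <- rec$metric[k]
    }
  }
  flagged
}

#' Edit the proton stoichiometry of Complex I
#'
#' Rescales the number of protons Complex I translocates across the
#' mitochondrial inner membrane per NADH oxidized, leaving the chemical
#' (redox) proton of the half-reaction untouched. The translocated pair is
#' recognized as the proton species appearing on both membrane sides: the
#' side with the positive coefficient receives the pumped protons, and its
#' coefficient equals the pumped count; the opposite side additionally
#' carries the chemical protons.
#'
#' @param model a `metabolic_model`.
#' @param protons_pumped new translocation stoichiometry per NADH
#'   (the scan points of interest are 0, 2 and 4; 4 is the
#'   reference stoichiometry).
#' @param complex_i_id reaction id of Complex I.
#' @return modified copy of the model.
#' @export
set_proton_stoichiometry <- function(model, protons_pumped,
                                     complex_i_id = "CPLX1_m") {
  stopifnot(protons_pumped >= 0)
  j <- rxn_index(model, complex_i_id)
  st <- model$reactions$stoichiometry[[j]]
  mets <- model$metabolites
  is_h <- vapply(names(st), function(id) {
    m <- mets[match(id, mets$id), ]
    identical(m$formula, "H") && isTRUE(m$charge == 1)
  }, logical(1))
  h_ids <- names(st)[is_h]
  if (length(h_ids) != 2L)
    stop("reaction '", complex_i_id,
         "' lacks a transmembrane proton pair (found ",
         length(h_ids), " proton species)")
  nadh <- mets$id[vapply(mets$id, function(id) grepl("^nadh", id), TRUE)]
  nadh_coef <- st[names(st) %in% nadh]
  if (length(nadh_coef) != 1L || nadh_coef >= 0)
    stop("reaction '", complex_i_id, "' does not oxidize NADH")
  per <- abs(nadh_coef)
  pos <- h_ids[st[h_ids] > 0]
  neg <- h_ids[st[h_ids] < 0]
  if (length(pos) != 1L || length(neg) != 1L)
    stop("reaction '", complex_i_id,
         "' protons do not form a translocated pair (need one side ",
         "consumed, one produced)")
  pumped_old <- st[[pos]] / per
  chemical <- -st[[neg]] / per - pumped_old
  if (chemical < 0)
    stop("reaction '", complex_i_id,
         "' proton coefficients are inconsistent with translocation")
  st[[pos]] <- protons_pumped * per
  st[[neg]] <- -(protons_pumped + chemical) * per
  model$reactions$stoichiometry[[j]] <- st[st != 0]
  model
}

#' Chemostat growth fitting under measured exchange rates
#'
#' Locks the measured uptake and secretion fluxes (within a relative band)
#' and maximizes growth, per protein-pool level. An infinite level stands
#' for the unaugmented (or effectively unconstrained) case.
#'
#' @param model a `metabolic_model` or `protein_pool_model`.
#' @param obs observation: list with `exchange_fluxes` (named vector,
#'   secretion positive) and `dilution_rate` (1/h), as produced by
#'   [generate_chemostat_observations()].
#' @param pool_levels pool levels to scan; ignored (a single unconstrained
#'   fit) when `model` is not pool-augmented.
#' @param band relative half-width of the flux lock (default 5%); `0`
#'   pins each exchange exactly.
#' @return named numeric vector of fitted growth rates (1/h) per level;
#'   `NA` where the locked problem is infeasible.
#' @export
chemostat_growth <- function(model, obs, pool_levels = c(0.1, 0.25, 1, Inf),
                             band = 0.05) {
  stopifnot(band >= 0)
  fl <- obs$exchange_fluxes
  lock <- function(m) {
    missing <- setdiff(names(fl), m$reactions$id)
    if (length(missing))
      stop("measured exchanges absent from model: ",
           paste(missing, collapse = ", "))
    for (id in names(fl)) {
      v <- fl[[id]]
      j <- match(id, m$reactions$id)
      # intersect the measurement band with the model's own bounds: a
      # measured rate cannot relax a physiological capacity
      lo <- max(min(v * (1 - band), v * (1 + band)),
                m$reactions$lower_bound[j])
      hi <- min(max(v * (1 - band), v * (1 + band)),
                m$reactions$upper_bound[j])
      if (lo > hi) return(NULL)
      m <- set_bounds(m, id, lower = lo, upper = hi)
    }
    m
  }
  fit_one <- function(m) {
    locked <- lock(m)
    if (is.null(locked)) return(NA_real_)
    sol <- fba(locked)
    if (sol$status == "optimal") sol$objective_value else NA_real_
  }
  if (!inherits(model, "protein_pool_model"))
    return(stats::setNames(fit_one(model), "Inf"))
  out <- vapply(pool_levels, function(lv)
    fit_one(set_pool_level(model, lv)$base), 0)
  stats::setNames(out, as.character(pool_levels))
}
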