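#' Fixture generators: a matched pair of compartmentalized yeast-core models
#'
#' `generate_toy_pair()` builds two small compartmentalized models (cytosol
#' `c`, mitochondrion `m`, extracellular `e`) sharing a lumped
#' glycolysis -> pyruvate backbone with fermentative (ethanol, acetate,
#' glycerol) and respiratory (lumped TCA, quinone pool, proton-translocating
#' chain, ATP synthase) branches, an ATP-costing biomass, and the
#' NADP-linked glutamate dehydrogenase (GDH; AKG + H+ + NADPH + NH4+ ->
#' GLU + H2O + NADP+) / isocitrate dehydrogenase (IDP; ICIT + NADP+ ->
#' AKG + CO2 + NADPH) shuttle pair.
#'
#' The *respirer* carries proton-pumping Complex I (4 H+ per NADH by
#' default), a mitochondrial folate-cycle analog (an ATP-free mitochondrial
#' route to the formyl units that the cytosolic route buys with one ATP),
#' and both compartmental placements of GDH and IDP. The *fermenter* keeps
#' only the non-pumping NDH-2 dehydrogenase, cytosolic GDH and mitochondrial
#' IDP. Neither model transports alpha-ketoglutarate out of the
#' mitochondrion, so the fermenter's only cytosolic NADPH source is the
#' NADP-linked acetaldehyde-to-acetate branch: its nitrogen assimilation
#' forces acetate production, the planted fermentation differentiator.
#'
#' All non-exchange reactions are elementally balanced (C, H, N, O, P and
#' charge), with protons tracked per compartment; the biomass macromolecule
#' is assigned the formula and charge that balance the biomass equation
#' exactly, so carbon accounting along simulated trajectories is closed by
#' construction.
#'
#' @param params a list of generator parameters; see [toy_pair_params()].
#' @return list with elements `respirer` and `fermenter`, both
#'   `metabolic_model` objects.
#' @export
generate_toy_pair <- function(params = toy_pair_params()) {
  p <- utils::modifyList(toy_pair_params(), params)
  stopifnot(p$protons_complex_i >= 0, p$atp_per_proton_quantum > 0,
            p$biomass_atp_cost > 0)
  respirer <- build_toy_model(p, species = "respirer")
  fermenter <- build_toy_model(p, species = "fermenter")
  chk <- fba(respirer)
  if (chk$status != "optimal" || chk$objective_value <= 1e-9)
    stop("toy-pair parameters make the respirer biomass infeasible")
  chk <- fba(fermenter)
  if (chk$status != "optimal" || chk$objective_value <= 1e-9)
    stop("toy-pair parameters make the fermenter biomass infeasible")
  list(respirer = respirer, fermenter = fermenter)
}

#' Default parameters of the toy model pair
#'
#' @param protons_complex_i protons translocated by Complex I per NADH
#'   (reference stoichiometry 4).
#' @param atp_per_proton_quantum protons flowing back through ATP synthase
#'   per ATP formed (3: one further proton is consumed chemically).
#' @param biomass_atp_cost mmol ATP hydrolyzed per unit biomass.
#' @param biomass_glu,biomass_pyr,biomass_for precursor coefficients of the
#'   biomass reaction (glutamate, pyruvate, formyl units).
#' @param maintenance_atp non-growth ATP maintenance demand, mmol/gDW/h.
#'   Its presence makes the inner problem infeasible once glucose can no
#'   longer cover maintenance, which is what terminates batch simulations.
#' @param nh4_uptake_bound ammonium supply rate cap in mmol/gDW/h. The
#'   default places nitrogen-limited growth between the two species' ATP-
#'   limited growth capacities, so that with Complex I present growth is
#'   nitrogen-limited (and the shuttle/folate side routes carry no marginal
#'   growth value), while without Complex I growth is ATP-limited.
#' @param include_shuttle_in_both_compartments named logical vector
#'   (`respirer`, `fermenter`): whether GDH and IDP occur in both
#'   compartments (respirer) or only in their single canonical compartment
#'   (fermenter: GDH cytosolic, IDP mitochondrial).
#' @param glucose_carbon carbon atoms per glucose (6; informational).
#' @param default_flux_bound magnitude used for unconstrained reactions.
#' @param seed integer seed recorded for provenance (the pair itself is
#'   deterministic; ensembles and tables draw from it).
#' @return named list of parameters.
#' @export
toy_pair_params <- function(protons_complex_i = 4L,
                            atp_per_proton_quantum = 3,
                            biomass_atp_cost = 130,
                            biomass_glu = 0.5,
                            biomass_pyr = 1,
                            biomass_for = 0.05,
                            maintenance_atp = 1,
                            nh4_uptake_bound = 0.19,
                            include_shuttle_in_both_compartments =
                              c(respirer = TRUE, fermenter = FALSE),
                            glucose_carbon = 6L,
                            default_flux_bound = 1000,
                            seed = 1L) {
  list(protons_complex_i = protons_complex_i,
       atp_per_proton_quantum = atp_per_proton_quantum,
       biomass_atp_cost = biomass_atp_cost,
       biomass_glu = biomass_glu, biomass_pyr = biomass_pyr,
       biomass_for = biomass_for,
       maintenance_atp = maintenance_atp,
       nh4_uptake_bound = nh4_uptake_bound,
       include_shuttle_in_both_compartments =
         include_shuttle_in_both_compartments,
       glucose_carbon = glucose_carbon,
       default_flux_bound = default_flux_bound,
       seed = seed)
}

# species formulas used for the elemental bookkeeping of the toy pair
toy_formulas <- function() {
  list(
    glc__D = c(C = 6, H = 12, O = 6, chg = 0),
    pyr    = c(C = 3, H = 3, O = 3, chg = -1),
    atp    = c(C = 10, H = 12, N = 5, O = 13, P = 3, chg = -4),
    adp    = c(C = 10, H = 12, N = 5, O = 10, P = 2, chg = -3),
    pi     = c(H = 1, O = 4, P = 1, chg = -2),
    h      = c(H = 1, chg = 1),
    h2o    = c(H = 2, O = 1, chg = 0),
    nad    = c(C = 21, H = 26, N = 7, O = 14, P = 2, chg = -1),
    nadh   = c(C = 21, H = 27, N = 7, O = 14, P = 2, chg = -2),
    nadp   = c(C = 21, H = 25, N = 7, O = 17, P = 3, chg = -3),
    nadph  = c(C = 21, H = 26, N = 7, O = 17, P = 3, chg = -4),
    o2     = c(O = 2, chg = 0),
    co2    = c(C = 1, O = 2, chg = 0),
    etoh   = c(C = 2, H = 6, O = 1, chg = 0),
    ac     = c(C = 2, H = 3, O = 2, chg = -1),
    glyc   = c(C = 3, H = 8, O = 3, chg = 0),
    akg    = c(C = 5, H = 4, O = 5, chg = -2),
    glu__L = c(C = 5, H = 8, N = 1, O = 4, chg = -1),
    icit   = c(C = 6, H = 5, O = 7, chg = -3),
    nh4    = c(H = 4, N = 1, chg = 1),
    q8     = c(C = 49, H = 74, O = 4, chg = 0),
    q8h2   = c(C = 49, H = 76, O = 4, chg = 0),
    forate = c(C = 1, H = 1, O = 2, chg = -1)  # formate ("for" is reserved)
  )
}

format_formula <- function(vec) {
  vec <- vec[setdiff(names(vec), "chg")]
  vec <- vec[vec != 0]
  ord <- intersect(c("C", "H", "N", "O", "P"), names(vec))
  paste0(vapply(ord, function(el) {
    n <- vec[[el]]
    if (n == 1) el else paste0(el, format(n, trim = TRUE))
  }, ""), collapse = "")
}

build_toy_model <- function(p, species) {
  B <- p$default_flux_bound
  fmls <- toy_formulas()
  shuttle_both <- isTRUE(p$include_shuttle_in_both_compartments[[species]])
  respirer <- species == "respirer"

  base_of <- function(id) sub("_(c|m|e)$", "", id)
  met_ids <- c(
    paste0(c("glc__D", "pyr", "atp", "adp", "pi", "h", "h2o", "nad", "nadh",
             "nadp", "nadph", "o2", "co2", "etoh", "ac", "glyc", "akg",
             "glu__L", "icit", "nh4", "forate"), "_c"),
    paste0(c("pyr", "atp", "adp", "pi", "h", "h2o", "nad", "nadh", "nadp",
             "nadph", "o2", "co2", "akg", "glu__L", "icit", "nh4", "q8",
             "q8h2", "forate"), "_m"),
    paste0(c("glc__D", "o2", "co2", "etoh", "ac", "glyc", "nh4", "h", "h2o"),
           "_e"),
    "biomass_c")

  rx <- list()
  add <- function(id, st, lb = 0, ub = B, name = id) {
    rx[[length(rx) + 1L]] <<- list(id = id, st = st, lb = lb, ub = ub,
                                   name = name)
  }

  q <- p$atp_per_proton_quantum      # H+ through ATP synthase per ATP
  nH <- p$protons_complex_i          # H+ pumped by Complex I per NADH

  ## central carbon ---------------------------------------------------------
  add("GLYLUMP_c", c(glc__D_c = -1, adp_c = -2, pi_c = -2, nad_c = -2,
                     pyr_c = 2, atp_c = 2, nadh_c = 2, h_c = 2, h2o_c = 2),
      name = "Glycolysis (lumped)")
  add("PDCADH_c", c(pyr_c = -1, h_c = -2, nadh_c = -1, etoh_c = 1,
                    co2_c = 1, nad_c = 1),
      name = "Pyruvate decarboxylase + alcohol dehydrogenase (lumped)")
  add("ALDNADP_c", c(pyr_c = -1, h2o_c = -1, nadp_c = -1, ac_c = 1,
                     co2_c = 1, h_c = 1, nadph_c = 1),
      name = "Pyruvate to acetate via NADP-linked acetaldehyde dehydrogenase")
  add("GLYCSYN_c", c(glc__D_c = -1, atp_c = -2, nadh_c = -2, h2o_c = -2,
                     glyc_c = 2, adp_c = 2, pi_c = 2, nad_c = 2),
      name = "Glycerol branch (lumped, ATP-costing)")
  add("PYRt_m", c(pyr_c = -1, h_c = -1, pyr_m = 1, h_m = 1),
      name = "Pyruvate-proton symport")
  add("PDHTCA_m", c(pyr_m = -1, h2o_m = -3, nad_m = -4, q8_m = -1,
                    co2_m = 3, nadh_m = 4, q8h2_m = 1, h_m = 3),
      name = "Pyruvate dehydrogenase + TCA cycle (lumped)")
  add("ICITSYN_m", c(pyr_m = -2, nad_m = -1, atp_m = -1, h2o_m = -2,
                     icit_m = 1, nadh_m = 1, adp_m = 1, pi_m = 1, h_m = 3),
      name = "Isocitrate synthesis (lumped carboxylase + citrate route)")

  ## NADP shuttle pair (Eq. 1 = GDH, Eq. 2 = IDP placements) ----------------
  add("IDP_m", c(icit_m = -1, nadp_m = -1, akg_m = 1, co2_m = 1,
                 nadph_m = 1),
      name = "Isocitrate:NADP+ oxidoreductase, mitochondrial")
  if (shuttle_both)
    add("IDP_c", c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1,
                   nadph_c = 1),
        name = "Isocitrate:NADP+ oxidoreductase, cytosolic")
  add("GDH_c", c(akg_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1,
                 glu__L_c = 1, h2o_c = 1, nadp_c = 1),
      name = "L-glutamate:NADP+ oxidoreductase, cytosolic")
  if (shuttle_both)
    add("GDH_m", c(akg_m = -1, nh4_m = -1, nadph_m = -1, h_m = -1,
                   glu__L_m = 1, h2o_m = 1, nadp_m = 1),
        name = "L-glutamate:NADP+ oxidoreductase, mitochondrial")
  add("IDH_c", c(icit_c = -1, nad_c = -1, akg_c = 1, co2_c = 1, nadh_c = 1),
      name = "Isocitrate:NAD+ oxidoreductase, cytosolic")

  ## respiratory chain (mitochondrial inner membrane) -----------------------
  add("NDH2_m", c(nadh_m = -1, q8_m = -1, h_m = -1, nad_m = 1, q8h2_m = 1),
      name = "Type II NADH dehydrogenase (non-pumping)")
  if (respirer)
    add("CPLX1_m",
        c(nadh_m = -1, q8_m = -1, h_m = -(nH + 1), nad_m = 1, q8h2_m = 1,
          h_c = nH),
        name = "Complex I NADH:ubiquinone oxidoreductase (proton pumping)")
  add("NDE_m", c(nadh_c = -1, h_c = -1, q8_m = -1, nad_c = 1, q8h2_m = 1),
      name = "External NADH dehydrogenase (cytosolic face)")
  add("CYTBO_m", c(q8h2_m = -1, o2_m = -0.5, h_m = -6, q8_m = 1, h2o_m = 1,
                   h_c = 6),
      name = "Terminal oxidase (lumped complexes III+IV)")
  add("ATPS_m", c(adp_m = -1, pi_m = -1, h_c = -(q + 1), atp_m = 1,
                  h2o_m = 1, h_m = q),
      name = "Mitochondrial ATP synthase")
  add("HLEAK_m", c(h_c = -1, h_m = 1),
      name = "Mitochondrial proton leak (wasteful)")

  ## formyl-unit (folate cycle analog) routes -------------------------------
  add("FORSYN_c", c(co2_c = -1, nadh_c = -1, atp_c = -1, h2o_c = -1,
                    forate_c = 1, nad_c = 1, adp_c = 1, pi_c = 1, h_c = 1),
      name = "Cytosolic formyl-unit synthesis (ATP-activated)")
  if (respirer)
    add("MTF_m", c(co2_m = -1, nadh_m = -1, forate_m = 1, nad_m = 1),
        name = "Mitochondrial folate-cycle formyl-unit synthesis (analog)")

  ## transporters ------------------------------------------------------------
  add("ATPt_m", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), lb = -B,
      name = "ATP/ADP translocase")
  add("PIt_m", c(pi_c = -1, h_c = -1, pi_m = 1, h_m = 1),
      name = "Phosphate-proton symport, mitochondrial")
  add("GLUt_m", c(glu__L_m = -1, glu__L_c = 1),
      name = "Glutamate export from mitochondrion")
  add("ICITt_m", c(icit_m = -1, icit_c = 1),
      name = "Isocitrate export from mitochondrion")
  add("FORt_m", c(forate_m = -1, forate_c = 1), lb = -B,
      name = "Formyl-unit carrier, mitochondrial")
  add("O2t_m", c(o2_c = -1, o2_m = 1), lb = -B)
  add("CO2t_m", c(co2_m = -1, co2_c = 1), lb = -B)
  add("H2Ot_m", c(h2o_m = -1, h2o_c = 1), lb = -B)
  add("NH4t_m", c(nh4_c = -1, nh4_m = 1), lb = -B)
  add("GLCt_c", c(glc__D_e = -1, glc__D_c = 1),
      name = "Glucose facilitated uptake")
  add("ETOHt_c", c(etoh_c = -1, etoh_e = 1), lb = -B)
  add("ACt_c", c(ac_c = -1, h_c = -1, ac_e = 1, h_e = 1),
      name = "Acetate-proton export")
  add("GLYCt_c", c(glyc_c = -1, glyc_e = 1), lb = -B)
  add("O2t_c", c(o2_e = -1, o2_c = 1), lb = -B)
  add("CO2t_c", c(co2_c = -1, co2_e = 1), lb = -B)
  add("H2Ot_c", c(h2o_c = -1, h2o_e = 1), lb = -B)
  add("NH4t_c", c(nh4_e = -1, nh4_c = 1))
  add("Ht_c", c(h_c = -1, h_e = 1), lb = -B,
      name = "Plasma-membrane proton diffusion (lumped)")

  ## maintenance and biomass --------------------------------------------------
  add("ATPM_c", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      lb = p$maintenance_atp,
      name = "Non-growth ATP maintenance")
  n <- p$biomass_atp_cost
  bio_st <- c(glu__L_c = -p$biomass_glu, pyr_c = -p$biomass_pyr,
              forate_c = -p$biomass_for, atp_c = -n, h2o_c = -n,
              biomass_c = 1, adp_c = n, pi_c = n, h_c = n)
  add("BIOMASS", bio_st, name = "Biomass (ATP + precursor sink)")
  add("SK_biomass_c", c(biomass_c = -1), name = "Biomass drain")

  ## exchanges ----------------------------------------------------------------
  add("EX_glc__D_e", c(glc__D_e = -1), lb = -10, ub = 0)
  add("EX_o2_e", c(o2_e = -1), lb = -B, ub = 0)
  add("EX_nh4_e", c(nh4_e = -1), lb = -p$nh4_uptake_bound, ub = 0)
  add("EX_etoh_e", c(etoh_e = -1), lb = 0, ub = B)
  add("EX_ac_e", c(ac_e = -1), lb = 0, ub = B)
  add("EX_glyc_e", c(glyc_e = -1), lb = 0, ub = B)
  add("EX_co2_e", c(co2_e = -1), lb = -B, ub = B)
  add("EX_h2o_e", c(h2o_e = -1), lb = -B, ub = B)
  add("EX_h_e", c(h_e = -1), lb = -B, ub = B)

  ## assemble -----------------------------------------------------------------
  # biomass formula/charge balancing the biomass equation exactly
  fmls$biomass <- local({
    tot <- c(C = 0, H = 0, N = 0, O = 0, P = 0, chg = 0)
    for (met in names(bio_st)) {
      if (met == "biomass_c") next
      f <- fmls[[base_of(met)]]
      for (el in names(f)) tot[el] <- tot[el] - bio_st[[met]] * f[[el]]
    }
    tot
  })
  comp_of <- function(id) sub(".*_(c|m|e)$", "\\1", id)
  mets <- data.frame(id = met_ids,
                     name = vapply(met_ids, base_of, ""),
                     compartment = vapply(met_ids, comp_of, ""),
                     stringsAsFactors = FALSE)
  mets$formula <- vapply(mets$id, function(id)
    format_formula(fmls[[base_of(id)]]), "")
  mets$charge <- vapply(mets$id, function(id)
    as.numeric(fmls[[base_of(id)]][["chg"]]), 0)

  rxns <- data.frame(id = vapply(rx, `[[`, "", "id"),
                     name = vapply(rx, `[[`, "", "name"),
                     lower_bound = vapply(rx, `[[`, 0, "lb"),
                     upper_bound = vapply(rx, `[[`, 0, "ub"),
                     gene_association = NA_character_,
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- lapply(rx, function(r) r$st[r$st != 0])

  metabolic_model(mets, rxns,
                  c(c = "cytosol", m = "mitochondrion", e = "extracellular"),
                  biomass_reaction = "BIOMASS")
}

#' Generate an ensemble of alternative reconstructions by reaction dropout
#'
#' Emulates the variability of alternative automated reconstructions of one
#' organism: each member independently drops every non-protected reaction
#' with probability `dropout_p`.
#'
#' @param model base `metabolic_model`.
#' @param dropout_p per-reaction dropout probability in `[0, 1)`.
#' @param n_models ensemble size.
#' @param protected_ids reactions never dropped (defaults to the biomass
#'   reaction and all exchanges).
#' @param seed integer seed; members are reproducible per seed.
#' @return list of `metabolic_model` objects.
#' @export
generate_ensemble <- function(model, dropout_p, n_models,
                              protected_ids = NULL, seed = 1L) {
  stopifnot(dropout_p >= 0, dropout_p < 1, n_models >= 1)
  if (is.null(protected_ids))
    protected_ids <- c(model$biomass_reaction, exchange_reactions(model))
  droppable <- !(model$reactions$id %in% protected_ids)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  lapply(seq_len(n_models), function(k) {
    drop <- droppable & (stats::runif(nrow(model$reactions)) < dropout_p)
    m <- model
    m$reactions <- m$reactions[!drop, , drop = FALSE]
    rownames(m$reactions) <- NULL
    used <- unique(unlist(lapply(m$reactions$stoichiometry, names)))
    m$metabolites <- m$metabolites[m$metabolites$id %in% used, , drop = FALSE]
    rownames(m$metabolites) <- NULL
    m
  })
}

# evaluate expressions under a temporary RNG state
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible(NULL)
  }
}

#' Generate a synthetic enzyme-parameter table
#'
#' Draws a log-uniform turnover number and a uniform molecular weight for
#' every reaction that should draw from the protein pool; exchanges, the
#' biomass reaction and its drain are flagged `draws_from_pool = FALSE`.
#' Stands in for a database-derived k_cat/MW table.
#'
#' Membrane-bound and respiratory-chain machines (multi-subunit complexes,
#' carriers) are drawn from a slow/heavy parameter class, soluble enzymes
#' from a fast/light class, reflecting the literature contrast between, say,
#' respiratory Complex I (circa 1 MDa, tens per second) and glycolytic
#' enzymes (tens to hundreds of kDa, hundreds per second). This cost
#' asymmetry is what makes respiration protein-expensive per ATP and drives
#' the fermentative shift under a scarce pool.
#'
#' @param model a `metabolic_model`.
#' @param kcat_range,kcat_range_membrane k_cat ranges in 1/h (log-uniform)
#'   for soluble and membrane/respiratory reactions. Defaults 3.6e5..3.6e6
#'   (100..1000 1/s) and 3.6e4..3.6e5 (10..100 1/s).
#' @param mw_range,mw_range_membrane molecular-weight ranges in g/mmol
#'   (uniform). Defaults 15..60 and 150..400.
#' @param membrane_ids reactions assigned to the membrane class; defaults to
#'   the toy pair's respiratory chain and mitochondrial carriers (ids ending
#'   in `_m`).
#' @param seed integer seed.
#' @return data.frame with columns `reaction_id`, `kcat_fwd`, `kcat_rev`,
#'   `kcat_unit`, `mw_g_per_mmol`, `draws_from_pool`.
#' @export
generate_enzyme_table <- function(model, kcat_range = c(3.6e5, 3.6e6),
                                  mw_range = c(15, 60),
                                  kcat_range_membrane = c(3.6e4, 3.6e5),
                                  mw_range_membrane = c(150, 400),
                                  membrane_ids = NULL, seed = 1L) {
  stopifnot(all(kcat_range > 0), all(mw_range > 0),
            all(kcat_range_membrane > 0), all(mw_range_membrane > 0))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  ids <- model$reactions$id
  if (is.null(membrane_ids)) membrane_ids <- ids[grepl("_m$", ids)]
  pooled <- !(ids %in% c(exchange_reactions(model), model$biomass_reaction,
                         "SK_biomass_c"))
  memb <- ids %in% membrane_ids
  n <- length(ids)
  lo <- ifelse(memb, kcat_range_membrane[1], kcat_range[1])
  hi <- ifelse(memb, kcat_range_membrane[2], kcat_range[2])
  kc <- exp(stats::runif(n, log(lo), log(hi)))
  mw <- stats::runif(n, ifelse(memb, mw_range_membrane[1], mw_range[1]),
                     ifelse(memb, mw_range_membrane[2], mw_range[2]))
  data.frame(reaction_id = ids,
             kcat_fwd = round(kc, 3),
             kcat_rev = round(kc, 3),
             kcat_unit = "1/h",
             mw_g_per_mmol = round(mw, 3),
             draws_from_pool = pooled,
             stringsAsFactors = FALSE)
}

#' Generate synthetic chemostat observations
#'
#' For each dilution rate, fixes growth to that rate, solves the model
#' lexicographically (biomass stage first, then the configured product
#' stages) to obtain a deterministic exchange-flux vector, perturbs the
#' measured exchanges with multiplicative Gaussian noise of total
#' coefficient of variation `noise_cv`, and emits one observation per rate.
#' Infeasible rates are skipped with a warning.
#'
#' The noise mimics the error structure of chemostat specific rates, which
#' are concentrations scaled by the same measured biomass: a dominant
#' common factor shared by all fluxes of one observation (biomass
#' normalization error, a fraction `common_variance_share` of the noise
#' variance) plus a smaller independent per-flux assay error.
#'
#' @param model a `metabolic_model`.
#' @param dilution_rates growth rates (1/h) to emulate.
#' @param noise_cv total coefficient of variation of the multiplicative
#'   noise per flux.
#' @param measured exchange reaction ids reported in each observation.
#' @param common_variance_share fraction of the noise variance carried by
#'   the shared biomass-normalization factor.
#' @param seed integer seed.
#' @return list of observations: each a list with `exchange_fluxes` (named
#'   vector, secretion positive) and `dilution_rate`.
#' @export
generate_chemostat_observations <- function(model, dilution_rates,
                                            noise_cv = 0,
                                            measured = c("EX_glc__D_e",
                                                         "EX_o2_e",
                                                         "EX_co2_e",
                                                         "EX_etoh_e",
                                                         "EX_ac_e"),
                                            common_variance_share = 0.7,
                                            seed = 1L) {
  stopifnot(common_variance_share >= 0, common_variance_share <= 1)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  lex <- default_lex(model)
  sd_common <- noise_cv * sqrt(common_variance_share)
  sd_flux <- noise_cv * sqrt(1 - common_variance_share)
  out <- list()
  for (mu in dilution_rates) {
    m <- set_bounds(model, model$biomass_reaction, lower = mu, upper = mu)
    sol <- lexicographic_fba(m, lex)
    if (sol$status != "optimal") {
      warning("dilution rate ", mu, " infeasible; skipped")
      next
    }
    fl <- sol$fluxes[measured]
    eta <- stats::rnorm(1, 0, sd_common)
    eps <- stats::rnorm(length(fl), 0, sd_flux)
    noisy <- fl * (1 + eta) * (1 + eps)
    out[[length(out) + 1L]] <-
      list(exchange_fluxes = stats::setNames(noisy, measured),
           dilution_rate = mu)
  }
  out
}
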