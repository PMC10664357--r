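test_that("essential candidates are flagged, reinserted and do not derail", {
  pair <- toy_pair_cached()
  # glycolysis is the only glucose entry: essential; the leak is a no-op
  scr <- cumulative_knockout_screen(pair$respirer,
                                    c("GLYLUMP_c", "GLYCSYN_c"))
  rec <- scr$records
  expect_true(rec$essential[rec$reaction_id == "GLYLUMP_c"])
  expect_true(rec$reinserted[rec$reaction_id == "GLYLUMP_c"])
  expect_false(rec$essential[rec$reaction_id == "GLYCSYN_c"])
  expect_equal(rec$growth[2], scr$baseline_growth, tolerance = 1e-9)
  # in the fermenter the single glutamate route is essential too
  scr2 <- cumulative_knockout_screen(pair$fermenter, "GDH_c")
  expect_true(scr2$records$essential[1])
  # ...but not in the respirer, which has the mitochondrial placement
  scr3 <- cumulative_knockout_screen(pair$respirer, "GDH_c")
  expect_false(scr3$records$essential[1])
})

test_that("knocking out a blocked reaction leaves the optimum unchanged", {
  pair <- toy_pair_cached()
  # IDP_m is flux-blocked in the fermenter (no mitochondrial NADPH sink)
  m <- batch_medium(pair$fermenter)
  expect_equal(fba(knockout(m, "IDP_m"))$objective_value,
               fba(m)$objective_value, tolerance = 1e-12)
})

test_that("growth screen flags the pumping and folate reactions only", {
  pair <- toy_pair_cached()
  cand <- reaction_set_difference(pair$respirer, pair$fermenter)
  scr <- cumulative_knockout_screen(pair$respirer, cand, metric = "growth")
  expect_setequal(screen_effects(scr), c("CPLX1_m", "MTF_m"))
  expect_false(any(scr$records$essential))
  # cumulative knockouts never increase growth
  expect_true(all(diff(c(scr$baseline_growth, scr$records$growth)) <= 1e-9))
  # determinism: identical inputs give identical records
  scr2 <- cumulative_knockout_screen(pair$respirer, cand, metric = "growth")
  expect_identical(scr$records, scr2$records)
})

test_that("Complex I is flagged under every candidate ordering", {
  # The folate analog and the shuttle pair only carry growth value once
  # Complex I is gone, so their flags depend on where Complex I falls in
  # the cumulative order; the Complex I flag itself is order-invariant.
  pair <- toy_pair_cached()
  cand <- reaction_set_difference(pair$respirer, pair$fermenter)
  set.seed(11)
  for (i in 1:5) {
    perm <- sample(cand)
    scr <- cumulative_knockout_screen(pair$respirer, perm, metric = "growth")
    eff <- screen_effects(scr)
    expect_true("CPLX1_m" %in% eff, label = paste(perm, collapse = ","))
    expect_false(any(scr$records$essential))
  }
})

test_that("fermentation screen implicates the shuttle pair jointly", {
  pair <- toy_pair_cached()
  r0 <- knockout(pair$respirer, "CPLX1_m")
  cand <- setdiff(reaction_set_difference(pair$respirer, pair$fermenter),
                  "CPLX1_m")
  scr <- cumulative_knockout_screen(r0, cand, metric = "fermentation")
  # order is IDP_c, GDH_m, MTF_m: the jump appears only at the second
  # shuttle knockout, once both placements are gone
  expect_identical(screen_effects(scr), "GDH_m")
  # single knockouts leave the metric unchanged
  one <- cumulative_knockout_screen(r0, "GDH_m", metric = "fermentation")
  expect_length(screen_effects(one), 0L)
  two <- cumulative_knockout_screen(r0, "IDP_c", metric = "fermentation")
  expect_length(screen_effects(two), 0L)
  # with both removed the fermenter's fermentation level is reached
  both <- knockout(r0, c("GDH_m", "IDP_c"))
  lex <- default_lex(both)
  ferm <- function(m) {
    s <- lexicographic_fba(batch_medium(m), lex)
    sum(s$stage_optima[c("EX_etoh_e", "EX_ac_e")])
  }
  expect_gt(ferm(both), ferm(r0))
  expect_equal(ferm(both), ferm(pair$fermenter), tolerance = 1e-3)
})

test_that("transplanting either shuttle reaction lowers fermentation", {
  pair <- toy_pair_cached()
  lex <- default_lex(pair$fermenter)
  ferm <- function(m) {
    s <- lexicographic_fba(batch_medium(m), lex)
    sum(s$stage_optima[c("EX_etoh_e", "EX_ac_e")])
  }
  f0 <- ferm(pair$fermenter)
  expect_lt(ferm(transplant_reaction(pair$respirer, pair$fermenter,
                                     "GDH_m")), f0)
  expect_lt(ferm(transplant_reaction(pair$respirer, pair$fermenter,
                                     "IDP_c")), f0)
})

test_that("proton stoichiometry editing rescales only the translocated pair", {
  pair <- toy_pair_cached()
  R <- pair$respirer
  same <- set_proton_stoichiometry(R, 4)
  expect_equal(same$reactions$stoichiometry[[
    match("CPLX1_m", same$reactions$id)]],
    R$reactions$stoichiometry[[match("CPLX1_m", R$reactions$id)]])
  two <- set_proton_stoichiometry(R, 2)
  st <- two$reactions$stoichiometry[[match("CPLX1_m", two$reactions$id)]]
  expect_equal(unname(st["h_c"]), 2)
  expect_equal(unname(st["h_m"]), -3)     # 2 translocated + 1 chemical
  expect_equal(unname(st["nadh_m"]), -1)  # redox half untouched
  zero <- set_proton_stoichiometry(R, 0)
  st0 <- zero$reactions$stoichiometry[[match("CPLX1_m", zero$reactions$id)]]
  expect_false("h_c" %in% names(st0))
  # growth is non-decreasing in protons pumped
  mu <- vapply(c(0, 2, 4), function(n)
    fba(batch_medium(set_proton_stoichiometry(R, n)))$objective_value, 0)
  expect_true(all(diff(mu) >= -1e-9))
  # a reaction without a transmembrane proton pair is rejected
  expect_error(set_proton_stoichiometry(R, 2, complex_i_id = "NDH2_m"),
               "pair")
  expect_error(set_proton_stoichiometry(R, 2, complex_i_id = "GLYLUMP_c"),
               "NADH|pair")
})

test_that("chemostat fitting is self-consistent and monotone in the pool", {
  pair <- toy_pair_cached()
  obs <- generate_chemostat_observations(pair$fermenter, c(0.1, 0.25),
                                         noise_cv = 0, seed = 1)
  for (o in obs) {
    mu <- chemostat_growth(pair$fermenter, o, band = 0)
    expect_equal(unname(mu), o$dilution_rate, tolerance = 1e-6)
  }
  tab <- generate_enzyme_table(pair$fermenter, seed = 3)
  pm <- suppressWarnings(augment_with_pool(pair$fermenter, tab, p_tot = 1))
  fits <- chemostat_growth(pm, obs[[1]], pool_levels = c(0.1, 0.25, 1, Inf),
                           band = 0.05)
  fits <- fits[!is.na(fits)]
  expect_true(all(diff(fits) >= -1e-9))
  # infeasible locks are reported as NA, not raised
  bad <- obs[[1]]
  bad$exchange_fluxes["EX_o2_e"] <- 5  # oxygen secretion: impossible
  expect_true(all(is.na(chemostat_growth(pair$fermenter, bad, band = 0))))
})

test_that("noisy chemostat recovery stays within ten percent", {
  # recovery is assessed near the respirer's nitrogen-limited ceiling,
  # where the physiological cap regularizes the growth fit
  pair <- toy_pair_cached()
  mu_true <- 0.37
  hits <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    o <- generate_chemostat_observations(pair$respirer, mu_true,
                                         noise_cv = 0.05, seed = 1000 + s)
    mu <- chemostat_growth(pair$respirer, o[[1]], band = 0.05)
    if (!is.na(mu) && abs(mu - mu_true) / mu_true <= 0.1) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
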