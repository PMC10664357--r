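pooled_chain <- function() {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "CONV", "EX_B"),
                     lower_bound = c(-20, 0, 0),
                     upper_bound = c(0, 1000, 1000),
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- list(c(A_c = -1), c(A_c = -1, B_c = 1), c(B_c = -1))
  metabolic_model(mets, rxns, c(c = "cytosol"), "EX_B")
}

entry <- function(id, kcat, mw, pool = TRUE, unit = "1/h", rev = NA) {
  data.frame(reaction_id = id, kcat_fwd = kcat, kcat_rev = rev,
             kcat_unit = unit, mw_g_per_mmol = mw, draws_from_pool = pool,
             stringsAsFactors = FALSE)
}

test_that("pool cap gives v_max = p_tot * kcat / MW for one pooled reaction", {
  pm <- suppressWarnings(
    augment_with_pool(pooled_chain(), entry("CONV", 100, 1), p_tot = 0.1))
  expect_equal(fba(pm$base, "CONV")$objective_value, 10, tolerance = 1e-9)
  # halving saturation halves the capacity
  pm2 <- suppressWarnings(
    augment_with_pool(pooled_chain(), entry("CONV", 100, 1), p_tot = 0.1,
                      saturation = 0.5))
  expect_equal(fba(pm2$base, "CONV")$objective_value, 5, tolerance = 1e-9)
})

test_that("kcat unit conversion and duplicate collapsing behave as documented", {
  tab <- rbind(entry("CONV", 100, 1),
               entry("CONV", 300, 3),
               entry("CONV", 200, 2))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_enzyme_table(tab, p)
  back <- read_enzyme_table(p)
  expect_equal(nrow(back), 1L)
  expect_equal(back$kcat_fwd, 200)       # median of candidates
  expect_equal(back$mw_g_per_mmol, 2)
  per_s <- read_enzyme_table({
    p2 <- withr::local_tempfile(fileext = ".tsv")
    write_enzyme_table(entry("CONV", 2, 1, unit = "1/s"), p2); p2
  })
  expect_equal(per_s$kcat_fwd, 7200)
  expect_identical(per_s$kcat_unit, "1/h")
})

test_that("invalid enzyme parameters are rejected", {
  expect_error(
    augment_with_pool(pooled_chain(), entry("CONV", -5, 1), 0.1),
    "non-positive")
  expect_error(
    augment_with_pool(pooled_chain(), entry("CONV", 100, 0), 0.1),
    "non-positive")
  expect_error(
    augment_with_pool(pooled_chain(), entry("GHOST", 100, 1), 0.1),
    "unknown reaction")
  expect_error(
    suppressWarnings(augment_with_pool(pooled_chain(),
                                       entry("CONV", 100, 1), -1)))
  # a pooled-candidate reaction without parameters: warn, or error in strict
  pair <- toy_pair_cached()
  expect_warning(augment_with_pool(pair$respirer, entry("GLYLUMP_c", 100, 1),
                                   0.1),
                 "no protein cost")
  expect_error(augment_with_pool(pair$respirer, entry("GLYLUMP_c", 100, 1),
                                 0.1, strict = TRUE),
               "no protein cost")
})

test_that("reversible pooled reactions split with partitioned bounds", {
  m <- pooled_chain()
  m <- set_bounds(m, "CONV", lower = -7)
  pm <- suppressWarnings(
    augment_with_pool(m, entry("CONV", 100, 1, rev = 50), p_tot = 0.1))
  expect_identical(pm$split_map$CONV,
                   c(forward = "CONV", backward = "CONV_REV"))
  rx <- pm$base$reactions
  expect_equal(rx$lower_bound[rx$id == "CONV"], 0)
  expect_equal(rx$upper_bound[rx$id == "CONV"], 1000)
  expect_equal(unname(unlist(rx[rx$id == "CONV_REV",
                                c("lower_bound", "upper_bound")])),
               c(0, 7))
  # backward stoichiometry is the negation plus its own pool cost
  st <- rx$stoichiometry[[which(rx$id == "CONV_REV")]]
  expect_equal(unname(st[c("A_c", "B_c")]), c(1, -1))
  expect_equal(unname(st["prot_pool_c"]), -1 / 50)
  # net flux of the split pair stays within the original bounds
  sol <- fba(pm$base, "EX_B")
  net <- sol$fluxes[["CONV"]] - sol$fluxes[["CONV_REV"]]
  expect_gte(net, -7 - 1e-9)
  expect_lte(net, 1000 + 1e-9)
})

test_that("pool level scaling is idempotent, monotone, and saturating", {
  pair <- toy_pair_cached()
  tab <- generate_enzyme_table(pair$respirer, seed = 1)
  pm <- suppressWarnings(augment_with_pool(pair$respirer, tab, p_tot = 0.25))
  pm_again <- set_pool_level(set_pool_level(pm, 0.25), 0.25)
  expect_identical(pm$base$reactions$upper_bound,
                   pm_again$base$reactions$upper_bound)
  growth <- vapply(c(0.1, 0.25, 1.0), function(lv)
    fba(batch_medium(set_pool_level(pm, lv)$base))$objective_value, 0)
  expect_true(all(diff(growth) >= -1e-9))
  # at a generous pool the uptake-limited unaugmented optimum is recovered
  unaug <- fba(batch_medium(pair$respirer))$objective_value
  expect_equal(fba(batch_medium(set_pool_level(pm, 1e9)$base))$objective_value,
               unaug, tolerance = 1e-6)
  expect_error(set_pool_level(pm, -1), "positive")
})

test_that("pool consumption never exceeds the cap at an optimum", {
  pair <- toy_pair_cached()
  tab <- generate_enzyme_table(pair$respirer, seed = 2)
  for (lv in c(0.1, 0.25)) {
    pm <- suppressWarnings(
      augment_with_pool(pair$respirer, tab, p_tot = lv))
    sol <- lexicographic_fba(batch_medium(pm$base), default_lex(pm$base))
    expect_identical(sol$status, "optimal")
    expect_lte(pool_usage(pm, sol), lv + 1e-9)
  }
})

test_that("equivalent-pool arithmetic follows the saturation convention", {
  expect_equal(equivalent_pool(0.448, 0.5), 0.224)
  expect_equal(round(equivalent_pool(0.448, 0.5), 2), 0.22)
  expect_equal(equivalent_pool(3.7, 1), 3.7)
  expect_equal(equivalent_pool(1.0, 0.25), 0.25)
  expect_error(equivalent_pool(-1, 0.5))
})
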