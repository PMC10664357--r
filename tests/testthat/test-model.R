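test_that("model validation catches structural defects", {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("R1", "R2"), lower_bound = 0,
                     upper_bound = 10, stringsAsFactors = FALSE)
  rxns$stoichiometry <- list(c(A_c = -1, B_c = 1), c(B_c = -1))
  expect_silent(metabolic_model(mets, rxns, c(c = "cytosol"), "R2"))
  expect_error(metabolic_model(mets, rxns, c(c = "cytosol"), "nope"),
               "biomass")
  bad <- rxns; bad$stoichiometry <- list(c(A_c = -1, X_c = 1), c(B_c = -1))
  expect_error(metabolic_model(mets, bad, c(c = "cytosol"), "R2"),
               "unknown metabolite")
  bad2 <- rxns; bad2$lower_bound[1] <- 20
  expect_error(metabolic_model(mets, bad2, c(c = "cytosol"), "R2"),
               "lower_bound")
  dup <- rbind(mets, mets[1, ])
  expect_error(metabolic_model(dup, rxns, c(c = "cytosol"), "R2"),
               "duplicate metabolite")
})

test_that("stoichiometric matrix drops boundary species and keeps shape", {
  m <- chain_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(3L, 5L))
  expect_equal(unname(S["A_c", "AtoB"]), -1)
  # a boundary metabolite is excluded from mass balance
  m$metabolites <- rbind(m$metabolites,
                         data.frame(id = "A_b", name = "A", compartment = "b",
                                    formula = NA, charge = NA))
  m$reactions$stoichiometry[[1]] <- c(A_c = -1, A_b = 1)
  S2 <- stoichiometric_matrix(m)
  expect_equal(nrow(S2), 3L)
  expect_false("A_b" %in% rownames(S2))
})

test_that("reversibility and exchange detection follow conventions", {
  pair <- toy_pair_cached()
  rev <- is_reversible(pair$respirer)
  expect_true(rev[["ATPt_m"]])
  expect_false(rev[["GLYLUMP_c"]])
  ex <- exchange_reactions(pair$respirer)
  expect_true(all(c("EX_glc__D_e", "EX_o2_e", "EX_etoh_e") %in% ex))
  expect_false("GLYLUMP_c" %in% ex)
  expect_true("SK_biomass_c" %in% ex)  # single-species drain
})

test_that("knockout closes bounds on a copy and errors on unknown ids", {
  m <- chain_model()
  k <- knockout(m, "AtoB")
  expect_equal(k$reactions$upper_bound[k$reactions$id == "AtoB"], 0)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "AtoB"], 1000)
  expect_error(knockout(m, "missing"), "unknown reaction")
  expect_equal(fba(knockout(m, "EX_B"))$objective_value, 0)
})

test_that("reaction set difference supports id and signature matching", {
  pair <- toy_pair_cached()
  expect_identical(reaction_set_difference(pair$respirer, pair$respirer),
                   character(0))
  d <- reaction_set_difference(pair$respirer, pair$fermenter)
  expect_setequal(d, c("GDH_m", "IDP_c", "CPLX1_m", "MTF_m"))
  # signature matching sees through renamed ids
  ren <- pair$fermenter
  i <- match("GLYLUMP_c", ren$reactions$id)
  ren$reactions$id[i] <- "GLYCOLYSIS_ALIAS"
  d_id <- reaction_set_difference(pair$respirer, ren, match = "id")
  expect_true("GLYLUMP_c" %in% d_id)
  d_sig <- reaction_set_difference(pair$respirer, ren, match = "signature")
  expect_false("GLYLUMP_c" %in% d_sig)
  expect_setequal(d_sig, d)
})

test_that("transplantation copies reactions with their metabolites", {
  pair <- toy_pair_cached()
  f2 <- transplant_reaction(pair$respirer, pair$fermenter, "CPLX1_m")
  expect_true("CPLX1_m" %in% f2$reactions$id)
  expect_false("CPLX1_m" %in%
                 reaction_set_difference(pair$respirer, f2))
  # transplant then knockout restores the original optimum
  g0 <- fba(batch_medium(pair$fermenter))$objective_value
  g1 <- fba(knockout(batch_medium(f2), "CPLX1_m"))$objective_value
  expect_equal(g1, g0, tolerance = 1e-9)
  # conflicting stoichiometry under one id is refused
  clash <- pair$respirer
  j <- match("NDH2_m", clash$reactions$id)
  clash$reactions$stoichiometry[[j]] <- c(nadh_m = -1, nad_m = 1, h_m = -1,
                                          q8_m = -1, q8h2_m = 1, h_c = 2)
  expect_error(transplant_reaction(clash, pair$fermenter, "NDH2_m"),
               "different stoichiometry")
})

test_that("JSON round trip is byte-stable and preserves the model", {
  pair <- toy_pair_cached()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(pair$respirer, p1)
  back <- read_model(p1)
  write_model(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(nrow(back$reactions), nrow(pair$respirer$reactions))
  expect_equal(fba(back)$objective_value,
               fba(pair$respirer)$objective_value, tolerance = 1e-9)
  expect_error(read_model(file.path(tempdir(), "absent.json")), "not found")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', bad)
  expect_error(read_model(bad), "compartments")
})

test_that("SBML round trip preserves structure, bounds and annotations", {
  pair <- toy_pair_cached()
  p <- withr::local_tempfile(fileext = ".xml")
  write_model(pair$respirer, p)
  back <- read_model(p)
  expect_equal(nrow(back$reactions), nrow(pair$respirer$reactions))
  expect_identical(back$biomass_reaction, "BIOMASS")
  expect_identical(back$metabolites$formula, pair$respirer$metabolites$formula)
  expect_identical(back$metabolites$charge, pair$respirer$metabolites$charge)
  expect_equal(back$reactions$lower_bound, pair$respirer$reactions$lower_bound)
  expect_equal(fba(back)$objective_value,
               fba(pair$respirer)$objective_value, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<notsbml/>", bad)
  expect_error(read_model(bad), "SBML")
})
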