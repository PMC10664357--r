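# Shared fixtures, built once per test run.

toy_pair_cached <- local({
  pair <- NULL
  function() {
    if (is.null(pair)) pair <<- generate_toy_pair()
    pair
  }
})

# medium used for steady-state screen checks: the batch starting state
batch_medium <- function(model) screen_medium(model)

# five-reaction linear chain: EX_A -> (A->B) -> EX_B plus a blocked branch
chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_c", "B_c", "C_c"),
                     name = c("A", "B", "C"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "AtoB", "EX_B", "AtoC", "EX_C"),
                     lower_bound = c(-uptake, 0, 0, 0, 0),
                     upper_bound = c(0, 1000, 1000, 0, 1000),
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- list(c(A_c = -1), c(A_c = -1, B_c = 1),
                             c(B_c = -1), c(A_c = -1, C_c = 1),
                             c(C_c = -1))
  metabolic_model(mets, rxns, c(c = "cytosol"), biomass_reaction = "EX_B")
}

# abstract single-compartment respirer small enough for vertex enumeration
micro_respirer <- function() {
  mets <- data.frame(
    id = c("glc", "pyr", "atp", "nadh", "o2", "etoh", "bio"),
    name = c("glc", "pyr", "atp", "nadh", "o2", "etoh", "bio"),
    compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_glc", "EX_o2", "GLY", "FERM", "RESP", "BIOMASS", "EX_bio",
           "EX_etoh"),
    lower_bound = c(-10, -10, 0, 0, 0, 0, 0, 0),
    upper_bound = c(0, 0, 1000, 1000, 1000, 1000, 1000, 1000),
    stringsAsFactors = FALSE)
  rxns$stoichiometry <- list(
    c(glc = -1), c(o2 = -1),
    c(glc = -1, pyr = 2, atp = 2, nadh = 2),
    c(pyr = -1, nadh = -1, etoh = 1),
    c(pyr = -1, nadh = -1, o2 = -3, atp = 8),
    c(atp = -10, pyr = -1, bio = 1),
    c(bio = -1), c(etoh = -1))
  metabolic_model(mets, rxns, c(c = "cytosol"),
                  biomass_reaction = "BIOMASS")
}

# random small networks for the oracle-equivalence property
random_network <- function(seed) {
  set.seed(seed)
  n_int <- sample(2:4, 1)                 # internal metabolites
  n_rxn <- sample(5:12, 1)
  met_ids <- paste0("m", seq_len(n_int))
  n_ex <- max(2, sample(2:3, 1))          # exchange columns
  rxns <- vector("list", n_rxn)
  ids <- paste0("r", seq_len(n_rxn))
  for (j in seq_len(n_rxn)) {
    if (j <= n_ex) {
      st <- stats::setNames(-1, met_ids[1 + (j - 1) %% n_int])
    } else {
      k <- sample(2:min(3, n_int), 1)
      picks <- sample(met_ids, k)
      st <- stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE),
                            picks)
      if (all(st > 0)) st[1] <- -st[1]
    }
    rxns[[j]] <- st
  }
  df <- data.frame(id = ids,
                   lower_bound = sample(c(0, -10), n_rxn, replace = TRUE),
                   upper_bound = 10, stringsAsFactors = FALSE)
  df$stoichiometry <- rxns
  mets <- data.frame(id = met_ids, name = met_ids, compartment = "c",
                     stringsAsFactors = FALSE)
  metabolic_model(mets, df, c(c = "cytosol"), biomass_reaction = ids[n_rxn])
}
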