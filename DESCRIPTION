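Package: dynefba
Title: Dynamic and Enzyme-Constrained Flux Balance Analysis for Comparative Yeast Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of compartmentalized genome-scale
    metabolic models, aimed at comparing respiratory and fermentative yeast
    phenotypes. Provides flux balance analysis (FBA) and lexicographic
    multi-objective FBA on a built-in bounded-variable simplex solver, batch
    dynamic FBA by the static optimization approach with stiff (BDF)
    integration, sMOMENT-style enzyme-constrained models with a finite
    protein pool, majority-vote consensus of model ensembles, and the
    comparative screens used to locate phenotype-differentiating reactions:
    cumulative knockout screens for growth and fermentation, reaction
    transplantation between models, respiratory Complex I proton-
    stoichiometry editing, and chemostat growth-rate fitting. Models are read
    and written as SBML Level 3 with the fbc package or a documented JSON
    dialect. A fixture generator emulates a matched pair of compartmentalized
    yeast-core models differing in Complex I and the compartment placement of
    the NADP-linked glutamate dehydrogenase / isocitrate dehydrogenase pair.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
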