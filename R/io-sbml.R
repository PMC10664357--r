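SBML_NS <- c(sbml = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- SBML_NS
  model_node <- xml2::xml_find_first(doc, "./sbml:model", ns)
  if (inherits(model_node, "xml_missing"))
    stop("SBML parse failure: no <model> element in '", path, "'")

  comp_nodes <- xml2::xml_find_all(
    model_node, "./sbml:listOfCompartments/sbml:compartment", ns)
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  comp_names <- xml2::xml_attr(comp_nodes, "name")
  comp_names[is.na(comp_names)] <- comp_ids[is.na(comp_names)]
  compartments <- stats::setNames(comp_names, comp_ids)

  sp_nodes <- xml2::xml_find_all(model_node,
                                 "./sbml:listOfSpecies/sbml:species", ns)
  if (!length(sp_nodes))
    stop("SBML parse failure: model has no species")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in%
    c("true", "1")
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = ifelse(boundary, "b",
                         xml2::xml_attr(sp_nodes, "compartment")),
    formula = xml2::xml_attr(sp_nodes, "fbc:chemicalFormula", ns),
    charge = suppressWarnings(
      as.numeric(xml2::xml_attr(sp_nodes, "fbc:charge", ns))),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  par_nodes <- xml2::xml_find_all(model_node,
                                  "./sbml:listOfParameters/sbml:parameter",
                                  ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model_node,
                                 "./sbml:listOfReactions/sbml:reaction", ns)
  if (!length(rx_nodes))
    stop("SBML parse failure: model has no reactions")
  parse_refs <- function(node, xpath, sign) {
    refs <- xml2::xml_find_all(node, xpath, ns)
    if (!length(refs)) return(numeric(0))
    stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                    xml2::xml_attr(refs, "species"))
  }
  bound_of <- function(node, attr, fallback) {
    pid <- xml2::xml_attr(node, paste0("fbc:", attr), ns)
    if (is.na(pid)) pid <- xml2::xml_attr(node, attr)
    if (!is.na(pid) && pid %in% names(pars)) return(pars[[pid]])
    fallback
  }
  rows <- lapply(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    rev <- xml2::xml_attr(node, "reversible") %in% c("true", "1")
    st <- c(parse_refs(node, "./sbml:listOfReactants/sbml:speciesReference",
                       -1),
            parse_refs(node, "./sbml:listOfProducts/sbml:speciesReference",
                       1))
    if (!length(st))
      stop("SBML parse failure: reaction '", id, "' has no species")
    gpa <- xml2::xml_find_first(node, ".//fbc:geneProductAssociation", ns)
    gene <- if (inherits(gpa, "xml_missing")) NA_character_ else
      paste(xml2::xml_attr(
        xml2::xml_find_all(gpa, ".//fbc:geneProductRef", ns),
        "fbc:geneProduct", ns), collapse = " or ")
    list(id = id, name = xml2::xml_attr(node, "name"),
         lower_bound = bound_of(node, "lowerFluxBound",
                                if (rev) -1000 else 0),
         upper_bound = bound_of(node, "upperFluxBound", 1000),
         gene_association = gene, st = st)
  })
  rxns <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    name = vapply(rows, function(r) r$name %||% r$id, ""),
    lower_bound = vapply(rows, `[[`, 0, "lower_bound"),
    upper_bound = vapply(rows, `[[`, 0, "upper_bound"),
    gene_association = vapply(rows, `[[`, "", "gene_association"),
    stringsAsFactors = FALSE)
  rxns$name[is.na(rxns$name)] <- rxns$id[is.na(rxns$name)]
  rxns$stoichiometry <- lapply(rows, `[[`, "st")

  active <- xml2::xml_attr(
    xml2::xml_find_first(model_node, "./fbc:listOfObjectives", ns),
    "fbc:activeObjective", ns)
  biomass <- NA_character_
  obj_nodes <- xml2::xml_find_all(
    model_node,
    "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (length(obj_nodes))
    biomass <- xml2::xml_attr(obj_nodes[[1]], "fbc:reaction", ns)
  if (is.na(biomass)) {
    guess <- grep("biomass", rxns$id, ignore.case = TRUE, value = TRUE)
    if (!length(guess))
      stop("validation error: no biomass reaction (no active fbc ",
           "objective and no id matching 'biomass')")
    biomass <- guess[1]
  }
  metabolic_model(mets, rxns, compartments, biomass)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS[["sbml"]], '" xmlns:fbc="',
           SBML_NS[["fbc"]],
           '" level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">')

  lines <- c(lines, "    <listOfCompartments>")
  for (i in seq_along(model$compartments))
    lines <- c(lines, sprintf(
      '      <compartment id="%s" name="%s" constant="true"/>',
      names(model$compartments)[i], esc(model$compartments[[i]])))
  if (any(model$metabolites$compartment == "b"))
    lines <- c(lines,
               '      <compartment id="b" name="boundary" constant="true"/>')
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$formula))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    if (!is.na(m$charge))
      extra <- paste0(extra, sprintf(' fbc:charge="%s"', num(m$charge)))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="%s" ',
             'constant="false"%s/>'),
      m$id, esc(m$name), m$compartment,
      if (m$compartment == "b") "true" else "false", extra))
  }
  lines <- c(lines, "    </listOfSpecies>")

  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  par_id <- function(v) paste0("fb_", gsub("[^0-9A-Za-z]", "_", num(v)))
  lines <- c(lines, "    <listOfParameters>")
  for (v in bounds)
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      par_id(v), num(v)))
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- r$stoichiometry[[1]]
    st <- st[order(names(st))]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" ',
             'fast="false" fbc:lowerFluxBound="%s" ',
             'fbc:upperFluxBound="%s">'),
      r$id, esc(r$name), if (r$lower_bound < 0) "true" else "false",
      par_id(r$lower_bound), par_id(r$upper_bound)))
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>")
      for (k in seq_along(reac))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          names(reac)[k], num(-reac[[k]])))
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (k in seq_along(prod))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          names(prod)[k], num(prod[[k]])))
      lines <- c(lines, "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  lines <- c(lines, sprintf(
    '    <fbc:listOfObjectives fbc:activeObjective="obj">'),
    sprintf('      <fbc:objective fbc:id="obj" fbc:type="%s">',
            model$objective_sense),
    "        <fbc:listOfFluxObjectives>",
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                   'fbc:coefficient="1"/>'), model$biomass_reaction),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>", "</sbml>")
  writeLines(lines, path, useBytes = TRUE)
}
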