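#' Read a metabolic model
#'
#' Reads SBML Level 3 (with the fbc package) or the package's JSON dialect.
#' The JSON dialect is a plain, self-contained schema: top-level keys
#' `compartments` (id to name object), `metabolites` and `reactions`
#' (arrays), `biomass_reaction` and `objective_sense`; every reaction
#' carries explicit `lower_bound`/`upper_bound` and a `stoichiometry`
#' object of signed coefficients (negative = consumed). See
#' `system.file("extdata", "toy_chain.json", package = "dynefba")` for a
#' worked example.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension when
#'   omitted.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("JSON parse failure in '", path, "': ",
                             conditionMessage(e)))
  for (key in c("compartments", "metabolites", "reactions"))
    if (is.null(doc[[key]]))
      stop("JSON model missing required element '", key, "'")
  if (is.null(doc$biomass_reaction))
    stop("JSON model missing required element 'biomass_reaction'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$compartment))
      stop("metabolite entry lacking 'id' or 'compartment'")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               formula = m$formula %||% NA_character_,
               charge = as.numeric(m$charge %||% NA_real_),
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry))
      stop("reaction entry lacking 'id' or 'stoichiometry'")
    if (is.null(r$lower_bound) || is.null(r$upper_bound))
      stop("reaction '", r$id, "' lacking mandatory bounds")
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               gene_association = r$gene_association %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  rxns$stoichiometry <- lapply(doc$reactions, function(r)
    vapply(r$stoichiometry, as.numeric, 0))
  metabolic_model(mets, rxns, unlist(doc$compartments),
                  doc$biomass_reaction,
                  doc$objective_sense %||% "maximize")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic model
#'
#' Writes the JSON dialect (stable key ordering, UTF-8) or SBML Level 3
#' Version 1 with fbc v2 flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- r$stoichiometry[[1]]
    st <- st[order(names(st))]
    out <- list(id = r$id, name = r$name,
                stoichiometry = as.list(st),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound)
    if (!is.na(r$gene_association))
      out$gene_association <- r$gene_association
    out
  })
  doc <- list(compartments = as.list(model$compartments),
              metabolites = mets, reactions = rxns,
              biomass_reaction = model$biomass_reaction,
              objective_sense = model$objective_sense)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, path, useBytes = TRUE)
}
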