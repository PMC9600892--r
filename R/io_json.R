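# JSON model dialect. The schema mirrors the SBML-FBC content model
# field-for-field so fixtures need no XML tooling:
#
# {
#   "model_id": "...",
#   "metabolites": [{"id","name","formula","compartment"}, ...],
#   "reactions":   [{"id","name","stoichiometry":{met:coef,...},
#                    "lower_bound","upper_bound","is_exchange"}, ...],
#   "biomass_reaction_id": "...",
#   "objective_reaction_id": "..."
# }
#
# Writing is canonical (fixed key order, metabolites and reactions in model
# order, full-precision numbers), so read -> write -> read is a fixed point
# and write(read(f)) is byte-stable.

#' Read a constraint-based model
#'
#' @param path file path.
#' @param format `"json"` for the package's JSON dialect, `"sbml_fbc"` for
#'   SBML Level 3 with the FBC package.
#' @return a validated `metabolic_network`.
#' @export
read_model <- function(path, format = c("json", "sbml_fbc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file does not exist: ", path)
  switch(format,
         json = read_model_json(path),
         sbml_fbc = read_model_sbml(path))
}

#' Write a constraint-based model
#'
#' @param net a `metabolic_network`.
#' @param path output file path.
#' @param format `"json"` or `"sbml_fbc"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(net, path, format = c("json", "sbml_fbc")) {
  format <- match.arg(format)
  switch(format,
         json = write_model_json(net, path),
         sbml_fbc = write_model_sbml(net, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON model '", path, "': ",
                             conditionMessage(e))
  )
  for (field in c("model_id", "metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("malformed model '", path, "': missing element '", field, "'")
    }
  }
  if (is.null(doc$biomass_reaction_id)) {
    stop("model '", path, "' declares no biomass reaction")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               formula = m$formula %||% NA_character_,
               compartment = m$compartment %||% "c",
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               is_exchange = isTRUE(r$is_exchange),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) {
    s <- unlist(r$stoichiometry)
    if (is.null(s)) s <- numeric(0)
    s
  })
  names(stoich) <- rxns$id
  metabolic_network(
    model_id = doc$model_id,
    metabolites = mets,
    reactions = rxns,
    stoichiometry = stoich,
    biomass_reaction_id = doc$biomass_reaction_id,
    objective_reaction_id = doc$objective_reaction_id %||%
      doc$biomass_reaction_id
  )
}

write_model_json <- function(net, path) {
  mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    m <- net$metabolites[i, ]
    list(id = m$id, name = m$name,
         formula = if (is.na(m$formula)) NULL else m$formula,
         compartment = m$compartment)
  })
  rxns <- lapply(seq_len(nrow(net$reactions)), function(i) {
    r <- net$reactions[i, ]
    s <- net$stoichiometry[[r$id]]
    s <- s[order(names(s))]
    s_json <- if (length(s)) as.list(s) else structure(list(), names = character(0))
    list(id = r$id, name = r$name,
         stoichiometry = s_json,
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         is_exchange = r$is_exchange)
  })
  doc <- list(model_id = net$model_id,
              metabolites = mets,
              reactions = rxns,
              biomass_reaction_id = net$biomass_reaction_id,
              objective_reaction_id = net$objective_reaction_id)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
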