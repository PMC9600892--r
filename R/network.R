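#' Construct a single-organism constraint-based metabolic network
#'
#' The container holds a stoichiometric model in the usual constraint-based
#' form: metabolites, reactions with bounds (mmol/gDW/h), a designated biomass
#' reaction and an objective reaction. Exchange reactions move a single
#' metabolite across the system boundary; by the standard COBRA sign
#' convention a negative exchange flux is uptake and a positive flux is
#' secretion.
#'
#' @param model_id character scalar identifying the model.
#' @param metabolites data.frame with columns `id`, `name`, `formula`,
#'   `compartment`. `formula` may be `NA` (treated as carbon-free).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `is_exchange`.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param biomass_reaction_id,objective_reaction_id reaction ids; the
#'   objective defaults to the biomass reaction.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(model_id, metabolites, reactions, stoichiometry,
                              biomass_reaction_id,
                              objective_reaction_id = biomass_reaction_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  net <- structure(
    list(
      model_id = as.character(model_id),
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      biomass_reaction_id = as.character(biomass_reaction_id),
      objective_reaction_id = as.character(objective_reaction_id)
    ),
    class = "metabolic_network"
  )
  validate_network(net)
}

#' Validate a metabolic network's structural invariants
#'
#' Checks that every stoichiometry key refers to a declared metabolite, that
#' `lower_bound <= upper_bound` for every reaction, that the biomass and
#' objective reactions exist, and that every exchange reaction touches exactly
#' one metabolite.
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly usable, after passing all checks.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mets <- net$metabolites
  rxns <- net$reactions
  req_m <- c("id", "name", "formula", "compartment")
  req_r <- c("id", "name", "lower_bound", "upper_bound", "is_exchange")
  if (!all(req_m %in% names(mets))) {
    stop("metabolites must have columns: ", paste(req_m, collapse = ", "))
  }
  if (!all(req_r %in% names(rxns))) {
    stop("reactions must have columns: ", paste(req_r, collapse = ", "))
  }
  if (anyDuplicated(mets$id)) stop("duplicated metabolite ids")
  if (anyDuplicated(rxns$id)) stop("duplicated reaction ids")
  if (!setequal(names(net$stoichiometry), rxns$id)) {
    stop("stoichiometry entries must match reaction ids exactly")
  }
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  for (rid in rxns$id) {
    coef <- net$stoichiometry[[rid]]
    unknown <- setdiff(names(coef), mets$id)
    if (length(unknown)) {
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!net$biomass_reaction_id %in% rxns$id) {
    stop("biomass reaction ", net$biomass_reaction_id, " not in model")
  }
  if (!net$objective_reaction_id %in% rxns$id) {
    stop("objective reaction ", net$objective_reaction_id, " not in model")
  }
  ex <- rxns$id[rxns$is_exchange]
  n_met <- vapply(net$stoichiometry[ex], function(s) sum(s != 0), integer(1))
  if (length(ex) && any(n_met != 1L)) {
    stop("exchange reaction(s) must touch exactly one metabolite: ",
         paste(ex[n_met != 1L], collapse = ", "))
  }
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$model_id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)\n", sep = "")
  cat("  biomass: ", x$biomass_reaction_id,
      "   objective: ", x$objective_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Dense stoichiometric matrix of a network
#'
#' @param net a `metabolic_network`.
#' @return numeric matrix S, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(net) {
  S <- matrix(0, nrow(net$metabolites), nrow(net$reactions),
              dimnames = list(net$metabolites$id, net$reactions$id))
  for (rid in net$reactions$id) {
    coef <- net$stoichiometry[[rid]]
    coef <- coef[coef != 0]
    if (length(coef)) S[names(coef), rid] <- coef
  }
  S
}

#' Metabolite carried by each exchange reaction
#'
#' @param net a `metabolic_network`.
#' @return named character vector: exchange reaction id -> metabolite id.
#' @export
exchange_metabolites <- function(net) {
  ex <- net$reactions$id[net$reactions$is_exchange]
  vapply(ex, function(rid) {
    s <- net$stoichiometry[[rid]]
    names(s)[s != 0][1L]
  }, character(1))
}

# Element counts from a chemical formula string like "C6H12O6" or "C5H8O4Fe".
# Returns a named integer vector; NA/empty formulas give an empty vector.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(integer(0))
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse chemical formula: ", formula)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  counts <- ifelse(nzchar(n), as.integer(n), 1L)
  tapply(counts, el, sum)[unique(el)]
}

#' Carbon atoms per molecule of each metabolite
#'
#' Metabolites without a formula are treated as carbon-free; their ids are
#' attached as the `"no_formula"` attribute so callers can log them.
#'
#' @param net a `metabolic_network`.
#' @return named numeric vector of carbon counts, one per metabolite.
#' @export
carbon_counts <- function(net) {
  out <- vapply(seq_len(nrow(net$metabolites)), function(i) {
    f <- net$metabolites$formula[i]
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    counts <- parse_formula(f)
    as.numeric(if ("C" %in% names(counts)) counts[["C"]] else 0)
  }, numeric(1))
  names(out) <- net$metabolites$id
  no_formula <- names(out)[is.na(out)]
  out[is.na(out)] <- 0
  attr(out, "no_formula") <- no_formula
  out
}

# lookup helpers -------------------------------------------------------------

rxn_index <- function(net, rid) {
  i <- match(rid, net$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", rid)
  i
}

#' Flux balance analysis on a single network
#'
#' Maximizes (default) or minimizes the flux through `objective` subject to
#' steady state (`S v = 0`) and the reaction bounds.
#'
#' @param net a `metabolic_network`.
#' @param objective reaction id; defaults to the network's objective reaction.
#' @param maximize logical.
#' @return list with `status`, `objective_value`, and named `fluxes`.
#' @export
fba <- function(net, objective = net$objective_reaction_id, maximize = TRUE) {
  S <- stoich_matrix(net)
  n <- ncol(S)
  obj <- numeric(n)
  obj[rxn_index(net, objective)] <- 1
  res <- solve_lp(obj,
                  Aeq = S, beq = numeric(nrow(S)),
                  lb = net$reactions$lower_bound,
                  ub = net$reactions$upper_bound,
                  maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, objective_value = NA_real_, fluxes = NULL))
  }
  fluxes <- res$x
  names(fluxes) <- net$reactions$id
  list(status = "optimal",
       objective_value = unname(fluxes[objective]),
       fluxes = fluxes)
}
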