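# Defined growth media. A medium lists the permitted uptakes (positive
# magnitudes, mmol/gDW/h); applying it closes uptake of every
# carbon-containing exchange it does not list, so the named carbon source is
# the only bulk carbon entering the system. Mineral/ion/vitamin exchanges
# (carbon-free) default to a large "in excess" uptake bound.

#' Construct a medium definition
#'
#' @param uptake_bounds named numeric vector: exchange reaction id ->
#'   maximum uptake magnitude (positive, mmol/gDW/h).
#' @param carbon_source_id exchange reaction id of the main carbon source;
#'   must appear in `uptake_bounds`.
#' @param excess_value default uptake magnitude applied to carbon-free
#'   nutrient exchanges not listed explicitly. 1000 mmol/gDW/h effectively
#'   removes the constraint.
#' @param export_bounds optional named numeric vector: exchange reaction id ->
#'   maximum secretion magnitude. Secretion is otherwise unconstrained; a 0
#'   entry closes an export (used to model metabolites that cannot leave the
#'   community environment).
#' @return a `medium` object.
#' @export
medium <- function(uptake_bounds, carbon_source_id, excess_value = 1000,
                   export_bounds = NULL) {
  uptake_bounds <- unlist(uptake_bounds)
  if (!carbon_source_id %in% names(uptake_bounds)) {
    stop("carbon_source_id '", carbon_source_id,
         "' is not listed in uptake_bounds")
  }
  if (any(uptake_bounds < 0)) stop("uptake bounds must be non-negative magnitudes")
  if (!is.null(export_bounds)) {
    export_bounds <- unlist(export_bounds)
    if (any(export_bounds < 0)) stop("export bounds must be non-negative")
  }
  structure(list(uptake_bounds = uptake_bounds,
                 carbon_source_id = carbon_source_id,
                 excess_value = as.numeric(excess_value),
                 export_bounds = export_bounds),
            class = "medium")
}

#' Apply a medium to a network
#'
#' Exchange reactions listed in the medium get lower bound
#' `-uptake_bounds[id]`. Unlisted carbon-containing exchanges are closed to
#' uptake (lower bound 0); unlisted carbon-free exchanges get lower bound
#' `-excess_value` ("in excess"). Secretion (upper) bounds are untouched
#' unless the medium lists the exchange in `export_bounds`.
#'
#' @param net a `metabolic_network`.
#' @param med a [medium()].
#' @return the constrained network. Metabolites lacking a formula are treated
#'   as carbon-free; their ids are recorded in the `"no_formula"` attribute.
#' @export
apply_medium <- function(net, med) {
  stopifnot(inherits(med, "medium"))
  ex_ids <- net$reactions$id[net$reactions$is_exchange]
  unknown <- setdiff(names(med$uptake_bounds), ex_ids)
  if (length(unknown)) {
    stop("medium refers to exchange reaction(s) absent from model '",
         net$model_id, "': ", paste(unknown, collapse = ", "))
  }
  carbon <- carbon_counts(net)
  ex_met <- exchange_metabolites(net)
  for (rid in ex_ids) {
    i <- rxn_index(net, rid)
    if (rid %in% names(med$uptake_bounds)) {
      net$reactions$lower_bound[i] <- -med$uptake_bounds[[rid]]
    } else if (carbon[[ex_met[[rid]]]] > 0) {
      net$reactions$lower_bound[i] <- 0
    } else {
      net$reactions$lower_bound[i] <- -med$excess_value
    }
    if (rid %in% names(med$export_bounds)) {
      net$reactions$upper_bound[i] <- med$export_bounds[[rid]]
    }
  }
  net <- validate_network(net)
  attr(net, "no_formula") <- attr(carbon, "no_formula")
  net
}

#' Read a medium definition from YAML
#'
#' Expected keys: `carbon_source_id`, `uptake_bounds` (map), optional
#' `excess_value` and `export_bounds`.
#'
#' @param path YAML file path.
#' @return a [medium()].
#' @export
read_medium_yaml <- function(path) {
  d <- yaml::read_yaml(path)
  medium(uptake_bounds = unlist(d$uptake_bounds),
         carbon_source_id = d$carbon_source_id,
         excess_value = d$excess_value %||% 1000,
         export_bounds = if (!is.null(d$export_bounds)) unlist(d$export_bounds))
}
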