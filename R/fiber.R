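# Fiber polymers (inulin- and xylan-like) are modeled as single pseudo-species
# with an average degree of polymerization (DP). Normalizing on carbon makes
# growth on fibers of different chain length comparable: one fiber unit
# carries average_dp x carbon_per_monomer carbon atoms and hydrolyzes to
# exactly average_dp monomer equivalents.

#' Describe a fiber polymer
#'
#' @param fiber_id metabolite id of the polymer pseudo-species.
#' @param monomer_id metabolite id of the hydrolysis product.
#' @param average_dp average degree of polymerization (monomer units per
#'   polymer molecule), positive integer.
#' @param carbon_per_monomer carbon atoms per monomer (6 for hexoses such as
#'   fructose, 5 for pentoses such as xylose).
#' @return a `fiber_spec` object. Its `carbon_total` field is the carbon
#'   content of one fiber unit, `average_dp * carbon_per_monomer`.
#' @export
fiber_spec <- function(fiber_id, monomer_id, average_dp, carbon_per_monomer) {
  average_dp <- as.integer(average_dp)
  carbon_per_monomer <- as.integer(carbon_per_monomer)
  stopifnot(average_dp > 0, carbon_per_monomer > 0)
  structure(list(fiber_id = fiber_id, monomer_id = monomer_id,
                 average_dp = average_dp,
                 carbon_per_monomer = carbon_per_monomer,
                 carbon_total = average_dp * carbon_per_monomer),
            class = "fiber_spec")
}

#' Normalize a network's fiber polymer on carbon
#'
#' Sets the fiber pseudo-species' formula to the carbon content implied by
#' the fiber description (`average_dp * carbon_per_monomer` carbons, see
#' [fiber_spec()]) and verifies that the
#' degradation reaction (any non-exchange reaction consuming the fiber)
#' releases exactly `average_dp` monomer equivalents with an exact carbon
#' balance. If the network has no degradation reaction, one is added
#' (`<fiber_id>_hydrolysis`: 1 fiber -> average_dp monomer).
#'
#' @param net a `metabolic_network` containing the fiber and monomer
#'   metabolites and a fiber exchange reaction.
#' @param fiber a [fiber_spec()].
#' @return the normalized network.
#' @export
normalize_fiber_polymer <- function(net, fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (!fiber$fiber_id %in% net$metabolites$id) {
    stop("fiber metabolite not in model: ", fiber$fiber_id)
  }
  if (!fiber$monomer_id %in% net$metabolites$id) {
    stop("monomer metabolite not in model: ", fiber$monomer_id)
  }
  mi <- match(fiber$fiber_id, net$metabolites$id)
  net$metabolites$formula[mi] <- paste0("C", fiber$carbon_total)

  ex_met <- exchange_metabolites(net)
  if (!fiber$fiber_id %in% ex_met) {
    stop("model has no exchange reaction for fiber ", fiber$fiber_id)
  }
  # degradation reaction: non-exchange consumer of the fiber
  degr <- Filter(function(rid) {
    s <- net$stoichiometry[[rid]]
    !net$reactions$is_exchange[rxn_index(net, rid)] &&
      fiber$fiber_id %in% names(s) && s[[fiber$fiber_id]] < 0
  }, net$reactions$id)

  if (!length(degr)) {
    hid <- paste0(fiber$fiber_id, "_hydrolysis")
    net <- apply_curation(net, curation_edit("add_reaction", list(
      id = hid, name = paste("hydrolysis of", fiber$fiber_id),
      stoichiometry = stats::setNames(
        c(-1, fiber$average_dp), c(fiber$fiber_id, fiber$monomer_id)),
      lower_bound = 0, upper_bound = 1000, is_exchange = FALSE),
      "auto-added fiber hydrolysis"))
    degr <- hid
  }

  carbon <- carbon_counts(net)
  for (rid in degr) {
    s <- net$stoichiometry[[rid]]
    imbalance <- sum(s * carbon[names(s)])
    if (abs(imbalance) > 1e-9) {
      stop("carbon-imbalanced fiber degradation reaction ", rid,
           ": net carbon ", imbalance, " per unit flux")
    }
    monomer_yield <- if (fiber$monomer_id %in% names(s)) {
      s[[fiber$monomer_id]] / -s[[fiber$fiber_id]]
    } else 0
    if (abs(monomer_yield - fiber$average_dp) > 1e-9) {
      stop("degradation reaction ", rid, " releases ", monomer_yield,
           " monomer equivalents per fiber; expected ", fiber$average_dp)
    }
  }
  validate_network(net)
}
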