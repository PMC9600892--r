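# SteadyCom-style community modeling.
#
# All members grow at a common rate mu; each member k has an abundance X_k
# (biomass fraction, sum fixed to the total, default 1) and absolute fluxes
# V_k (mmol/h per unit total community biomass) constrained by
#   S_k V_k = 0,  LB_jk X_k <= V_jk <= UB_jk X_k,  V_biomass,k = mu X_k.
# Members interact through a shared extracellular pool: each member exchange
# reaction transfers its metabolite to the pool, and every pool metabolite p
# has a community exchange flux e_p (positive = export to the environment,
# negative = uptake from the medium) closing the balance
#   sum_k V_ex(k,p) - e_p = 0.
# For fixed mu the whole system is a linear program; the maximum balanced
# community growth rate is located by bisection over the feasibility LP.

#' Assemble a community model from member networks
#'
#' @param members named list of `metabolic_network` objects; the names are
#'   the member tags.
#' @param med a [medium()] applied at the community pool boundary. Its
#'   `uptake_bounds`/`export_bounds` are keyed by community exchange ids of
#'   the form `EX_<pool metabolite id>`.
#' @param pool_map optional named list (one per member) mapping member
#'   exchange reaction ids to pool metabolite ids. By default each exchange
#'   reaction's own metabolite id is the pool id, so members sharing
#'   extracellular metabolite ids are automatically coupled.
#' @return a `community_model`.
#' @export
assemble_community <- function(members, med, pool_map = NULL) {
  stopifnot(length(members) >= 1, inherits(med, "medium"))
  if (is.null(names(members)) || any(!nzchar(names(members)))) {
    stop("members must be a named list (names are the member tags)")
  }
  if (anyDuplicated(names(members))) stop("duplicated member tags")
  for (m in members) validate_network(m)

  if (is.null(pool_map)) {
    pool_map <- lapply(members, exchange_metabolites)
  } else {
    for (tag in names(members)) {
      ex_ids <- members[[tag]]$reactions$id[members[[tag]]$reactions$is_exchange]
      missing <- setdiff(ex_ids, names(pool_map[[tag]]))
      if (length(missing)) {
        stop("pool_map for member '", tag,
             "' does not cover exchange reaction(s): ",
             paste(missing, collapse = ", "))
      }
    }
  }
  pool_mets <- sort(unique(unlist(pool_map, use.names = FALSE)))
  # pool metabolite formulas, taken from the first member declaring them
  formulas <- stats::setNames(rep(NA_character_, length(pool_mets)), pool_mets)
  for (m in members) {
    hit <- m$metabolites$id %in% pool_mets & !is.na(m$metabolites$formula)
    formulas[m$metabolites$id[hit]] <- m$metabolites$formula[hit]
  }
  unknown <- setdiff(names(med$uptake_bounds), paste0("EX_", pool_mets))
  if (length(unknown)) {
    stop("medium refers to community exchange(s) with no pool metabolite: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(members = members, medium = med, pool_map = pool_map,
                 pool_mets = pool_mets, pool_formulas = formulas),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$members), " members: ",
      paste(names(x$members), collapse = ", "), "\n", sep = "")
  cat("  shared pool metabolites: ", length(x$pool_mets), "\n", sep = "")
  invisible(x)
}

#' Describe a simulation scenario
#'
#' @param mu_exp community growth rate to impose (h^-1), e.g. an
#'   experimentally observed rate.
#' @param fiber_id pool metabolite id of the fiber carbon source.
#' @param suboptimality_factor fractional growth relaxation used to widen the
#'   fiber budget (0.05 = budget allowing 5% faster growth).
#' @param total_abundance total community biomass the abundances sum to.
#' @param fixed_abundances optional named numeric vector pinning member
#'   abundances (names = member tags).
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(mu_exp, fiber_id, suboptimality_factor = 0.05,
                          total_abundance = 1, fixed_abundances = NULL) {
  stopifnot(mu_exp > 0, suboptimality_factor >= 0, total_abundance > 0)
  structure(list(mu_exp = mu_exp, fiber_id = fiber_id,
                 suboptimality_factor = suboptimality_factor,
                 total_abundance = total_abundance,
                 fixed_abundances = fixed_abundances),
            class = "scenario_spec")
}

# --- LP assembly ------------------------------------------------------------

# Variable layout: member fluxes (named "<tag>.<rxn>"), abundances
# ("X.<tag>"), pool exchanges ("EX.<met>"). Returns the constraint system at
# fixed mu as Aeq x = beq, Aleq x <= bleq, lb <= x <= ub.
community_lp <- function(cm, mu, total_abundance = 1,
                         fixed_abundances = NULL, fiber_budget = NULL,
                         fiber_id = NULL, big = 1000) {
  tags <- names(cm$members)
  n_flux <- vapply(cm$members, function(m) nrow(m$reactions), integer(1))
  flux_names <- unlist(lapply(tags, function(tag) {
    paste0(tag, ".", cm$members[[tag]]$reactions$id)
  }))
  ab_names <- paste0("X.", tags)
  ex_names <- paste0("EX.", cm$pool_mets)
  vars <- c(flux_names, ab_names, ex_names)
  n <- length(vars)
  idx <- stats::setNames(seq_len(n), vars)

  lb <- numeric(n); ub <- numeric(n)
  # flux boxes: X in [0, total] times reaction bounds
  pos <- 1L
  for (tag in tags) {
    r <- cm$members[[tag]]$reactions
    k <- nrow(r)
    lb[pos:(pos + k - 1)] <- pmin(r$lower_bound, 0) * max(total_abundance, 1)
    ub[pos:(pos + k - 1)] <- pmax(r$upper_bound, 0) * max(total_abundance, 1)
    pos <- pos + k
  }
  lb[idx[ab_names]] <- 0
  ub[idx[ab_names]] <- total_abundance
  # pool exchange bounds from the medium
  med <- cm$medium
  for (p in cm$pool_mets) {
    exid <- paste0("EX_", p)
    j <- idx[[paste0("EX.", p)]]
    carbon <- if (is.na(cm$pool_formulas[[p]])) 0 else {
      cc <- parse_formula(cm$pool_formulas[[p]])
      if ("C" %in% names(cc)) cc[["C"]] else 0
    }
    lb[j] <- if (exid %in% names(med$uptake_bounds)) {
      -med$uptake_bounds[[exid]]
    } else if (carbon > 0) 0 else -med$excess_value
    ub[j] <- if (exid %in% names(med$export_bounds)) {
      med$export_bounds[[exid]]
    } else big
  }
  if (!is.null(fiber_budget)) {
    j <- idx[[paste0("EX.", fiber_id)]]
    if (is.null(j)) stop("fiber metabolite not in community pool: ", fiber_id)
    lb[j] <- max(lb[j], -fiber_budget)
  }

  eq_rows <- list(); beq <- numeric(0)
  le_rows <- list(); ble <- numeric(0)
  add_eq <- function(coef_idx, coef_val, rhs) {
    row <- numeric(n); row[coef_idx] <- coef_val
    eq_rows[[length(eq_rows) + 1L]] <<- row
    beq[length(beq) + 1L] <<- rhs
  }
  add_le <- function(coef_idx, coef_val, rhs) {
    row <- numeric(n); row[coef_idx] <- coef_val
    le_rows[[length(le_rows) + 1L]] <<- row
    ble[length(ble) + 1L] <<- rhs
  }

  # member steady state
  for (tag in tags) {
    m <- cm$members[[tag]]
    S <- stoich_matrix(m)
    cols <- idx[paste0(tag, ".", colnames(S))]
    for (i in seq_len(nrow(S))) {
      nz <- which(S[i, ] != 0)
      if (length(nz)) add_eq(cols[nz], S[i, nz], 0)
    }
  }
  # pool balances: sum_k v_ex(k,p) - e_p = 0
  for (p in cm$pool_mets) {
    coef_idx <- integer(0); coef_val <- numeric(0)
    for (tag in tags) {
      pm <- cm$pool_map[[tag]]
      ex <- names(pm)[pm == p]
      if (length(ex)) {
        coef_idx <- c(coef_idx, idx[paste0(tag, ".", ex)])
        coef_val <- c(coef_val, rep(1, length(ex)))
      }
    }
    coef_idx <- c(coef_idx, idx[[paste0("EX.", p)]])
    coef_val <- c(coef_val, -1)
    add_eq(coef_idx, coef_val, 0)
  }
  # biomass coupling and abundance scaling of bounds
  for (tag in tags) {
    m <- cm$members[[tag]]
    xj <- idx[[paste0("X.", tag)]]
    bj <- idx[[paste0(tag, ".", m$biomass_reaction_id)]]
    add_eq(c(bj, xj), c(1, -mu), 0)
    for (i in seq_len(nrow(m$reactions))) {
      vj <- idx[[paste0(tag, ".", m$reactions$id[i])]]
      ubi <- m$reactions$upper_bound[i]
      lbi <- m$reactions$lower_bound[i]
      if (ubi != 0) add_le(c(vj, xj), c(1, -ubi), 0)
      if (lbi != 0) add_le(c(vj, xj), c(-1, lbi), 0)
    }
  }
  # abundance normalization (and optional pinning)
  add_eq(idx[ab_names], rep(1, length(tags)), total_abundance)
  if (!is.null(fixed_abundances)) {
    for (tag in names(fixed_abundances)) {
      add_eq(idx[[paste0("X.", tag)]], 1, fixed_abundances[[tag]])
    }
  }

  list(Aeq = do.call(rbind, eq_rows), beq = beq,
       Aleq = if (length(le_rows)) do.call(rbind, le_rows) else NULL,
       bleq = if (length(ble)) ble else NULL,
       lb = lb, ub = ub, vars = vars, idx = idx, mu = mu,
       tags = tags, big = big)
}

# Solve the community LP with a given objective vector; returns solve_lp()
# output plus the lp description.
community_solve <- function(lp, obj = NULL, maximize = FALSE) {
  if (is.null(obj)) obj <- numeric(length(lp$vars))
  res <- solve_lp(obj, lp$Aeq, lp$beq, lp$Aleq, lp$bleq, lp$lb, lp$ub,
                  maximize = maximize, big = lp$big)
  res$lp <- lp
  res
}

# Exchange-flux variable indices of a community lp
exchange_var_idx <- function(cm, lp) {
  out <- integer(0)
  for (tag in lp$tags) {
    ex <- names(cm$pool_map[[tag]])
    out <- c(out, lp$idx[paste0(tag, ".", ex)])
  }
  out
}

# Minimize sum of absolute member exchange fluxes subject to the lp system
# plus optional pinned variables. Resolves LP degeneracy at a reported
# optimum into a parsimonious witness. Pins are enforced through tight box
# bounds (width 2*pin_tol) rather than equality rows: pinning exactly on the
# optimal face makes the simplex tableau maximally degenerate.
min_total_exchange <- function(cm, lp, pin_idx = integer(0),
                               pin_val = numeric(0), pin_tol = 1e-7) {
  ex_idx <- exchange_var_idx(cm, lp)
  n <- length(lp$vars); m <- length(ex_idx)
  for (i in seq_along(pin_idx)) {
    lp$lb[pin_idx[i]] <- pin_val[i] - pin_tol
    lp$ub[pin_idx[i]] <- pin_val[i] + pin_tol
  }
  pad <- function(A) if (is.null(A)) NULL else cbind(A, matrix(0, nrow(A), m))
  Aeq <- pad(lp$Aeq); beq <- lp$beq
  Aleq <- pad(lp$Aleq); bleq <- lp$bleq
  for (i in seq_len(m)) {
    r1 <- numeric(n + m); r1[ex_idx[i]] <- 1; r1[n + i] <- -1   # v - t <= 0
    r2 <- numeric(n + m); r2[ex_idx[i]] <- -1; r2[n + i] <- -1  # -v - t <= 0
    Aleq <- rbind(Aleq, r1, r2); bleq <- c(bleq, 0, 0)
  }
  obj <- c(numeric(n), rep(1, m))
  res <- solve_lp(obj, Aeq, beq, Aleq, bleq,
                  lb = c(lp$lb, numeric(m)),
                  ub = c(lp$ub, rep(lp$big * 2, m)),
                  big = lp$big)
  if (res$status != "optimal") return(NULL)
  res$x <- res$x[seq_len(n)]
  names(res$x) <- lp$vars
  res$lp <- lp
  res
}

# Package an LP witness as a steadycom_solution
as_steadycom_solution <- function(cm, lp, x, fiber_id = NULL) {
  names(x) <- lp$vars
  tags <- lp$tags
  abundances <- stats::setNames(x[paste0("X.", tags)], tags)
  member_fluxes <- lapply(tags, function(tag) {
    r <- cm$members[[tag]]$reactions$id
    stats::setNames(unname(x[paste0(tag, ".", r)]), r)
  })
  names(member_fluxes) <- tags
  ex_rows <- do.call(rbind, lapply(tags, function(tag) {
    pm <- cm$pool_map[[tag]]
    data.frame(member = tag, reaction = names(pm),
               metabolite = unname(pm),
               flux = unname(x[paste0(tag, ".", names(pm))]),
               stringsAsFactors = FALSE)
  }))
  pool_ex <- stats::setNames(x[paste0("EX.", cm$pool_mets)], cm$pool_mets)
  fiber_uptake <- if (!is.null(fiber_id)) {
    -unname(pool_ex[[fiber_id]])
  } else NA_real_
  structure(list(mu = lp$mu, abundances = abundances,
                 member_fluxes = member_fluxes,
                 exchange_fluxes = ex_rows,
                 pool_exchanges = pool_ex,
                 fiber_uptake = fiber_uptake,
                 raw = x),
            class = "steadycom_solution")
}

#' @export
print.steadycom_solution <- function(x, ...) {
  cat("<steadycom_solution> mu = ", format(x$mu, digits = 7), " h^-1\n",
      sep = "")
  cat("  abundances: ",
      paste(sprintf("%s = %.4f", names(x$abundances), x$abundances),
            collapse = ", "), "\n", sep = "")
  if (is.finite(x$fiber_uptake)) {
    cat("  fiber uptake: ", format(x$fiber_uptake, digits = 7), " mmol/h\n",
        sep = "")
  }
  invisible(x)
}

# --- SteadyCom operations ---------------------------------------------------

#' Maximum balanced community growth rate
#'
#' Locates, by bisection over the feasibility LP, the largest common growth
#' rate mu for which the community constraint system admits a solution, and
#' attaches a witness flux distribution (degeneracy resolved by minimizing
#' total absolute exchange flux).
#'
#' @param cm a `community_model`.
#' @param total_abundance total community biomass (default 1, so abundances
#'   are relative fractions).
#' @param mu_tolerance bisection convergence tolerance (h^-1).
#' @param mu_max upper end of the bisection bracket.
#' @param fiber_id optional pool metabolite id to report fiber uptake for.
#' @param fiber_budget optional cap on that metabolite's community uptake.
#' @return a `steadycom_solution` with the located `mu`.
#' @export
max_community_growth <- function(cm, total_abundance = 1,
                                 mu_tolerance = 1e-6, mu_max = 10,
                                 fiber_id = NULL, fiber_budget = NULL) {
  feasible_at <- function(mu) {
    lp <- community_lp(cm, mu, total_abundance,
                       fiber_budget = fiber_budget, fiber_id = fiber_id)
    res <- community_solve(lp)
    list(ok = res$status == "optimal", res = res, lp = lp)
  }
  lo <- feasible_at(0)
  if (!lo$ok) stop("community infeasible even at zero growth")
  hi <- feasible_at(mu_max)
  if (hi$ok) {
    stop("community growth is not limited below mu = ", mu_max,
         "; no limiting uptake bound")
  }
  mu_lo <- 0; mu_hi <- mu_max
  best <- lo
  while (mu_hi - mu_lo > mu_tolerance) {
    mid <- (mu_lo + mu_hi) / 2
    at <- feasible_at(mid)
    if (at$ok) {
      mu_lo <- mid; best <- at
    } else {
      mu_hi <- mid
    }
  }
  refined <- min_total_exchange(cm, best$lp)
  x <- if (!is.null(refined)) refined$x else best$res$x
  as_steadycom_solution(cm, best$lp, x, fiber_id = fiber_id)
}

#' Minimal community fiber uptake at a fixed growth rate
#'
#' Minimizes the community uptake magnitude of the fiber carbon source
#' subject to all SteadyCom constraints at `mu_fixed`. The reported flux
#' distribution additionally minimizes total absolute exchange flux at the
#' optimal uptake, resolving LP degeneracy.
#'
#' @param cm a `community_model`.
#' @param mu_fixed imposed community growth rate (h^-1).
#' @param fiber_id pool metabolite id of the fiber.
#' @param total_abundance total community biomass.
#' @return a `steadycom_solution`; its `fiber_uptake` is the minimized
#'   uptake (mmol/h, positive magnitude).
#' @export
min_fiber_uptake <- function(cm, mu_fixed, fiber_id, total_abundance = 1) {
  lp <- community_lp(cm, mu_fixed, total_abundance)
  j <- lp$idx[[paste0("EX.", fiber_id)]]
  if (is.null(j)) stop("fiber metabolite not in community pool: ", fiber_id)
  obj <- numeric(length(lp$vars)); obj[j] <- 1
  res <- community_solve(lp, obj, maximize = TRUE)  # least-negative e_fiber
  if (res$status != "optimal") {
    best_mu <- tryCatch(
      max_community_growth(cm, total_abundance)$mu,
      error = function(e) NA_real_)
    stop("community infeasible at mu = ", mu_fixed,
         if (is.finite(best_mu)) paste0("; maximum feasible mu ~ ",
                                        format(best_mu, digits = 7)))
  }
  refined <- min_total_exchange(cm, lp, pin_idx = j, pin_val = res$x[j])
  x <- if (!is.null(refined)) refined$x else res$x
  sol <- as_steadycom_solution(cm, lp, x, fiber_id = fiber_id)
  sol$fiber_uptake <- -unname(res$x[j])  # primary optimum, not the witness
  sol
}

#' Suboptimal fiber budget
#'
#' The fiber uptake that would allow the community to grow
#' `(1 + suboptimality_factor)` times faster than the scenario's experimental
#' rate. Downstream variability analyses run at the experimental rate with
#' fiber uptake at most this budget, which opens flux variability around the
#' optimal state.
#'
#' @param cm a `community_model`.
#' @param scenario a [scenario_spec()].
#' @return the budget u' (mmol/h, positive magnitude).
#' @export
suboptimal_budget <- function(cm, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  mu_target <- (1 + scenario$suboptimality_factor) * scenario$mu_exp
  sol <- tryCatch(
    min_fiber_uptake(cm, mu_target, scenario$fiber_id,
                     scenario$total_abundance),
    error = function(e) stop("suboptimal growth target mu = ", mu_target,
                             " is unreachable: ", conditionMessage(e),
                             call. = FALSE))
  sol$fiber_uptake
}

#' Community flux variability analysis
#'
#' For each requested quantity, minimizes and maximizes its value over the
#' community polytope at the scenario's experimental growth rate with fiber
#' uptake bounded by the suboptimal budget (`<=` u', not pinned).
#'
#' @param cm a `community_model`.
#' @param scenario a [scenario_spec()].
#' @param quantities character vector of variable names: `"X.<member>"` for
#'   abundances, `"<member>.<reaction>"` for member fluxes, `"EX.<met>"` for
#'   community exchanges. Default: all abundances and member exchange fluxes.
#' @param fiber_budget the budget u'; computed via [suboptimal_budget()] when
#'   not supplied.
#' @return data.frame with columns `quantity`, `min`, `max`.
#' @export
community_fva <- function(cm, scenario, quantities = NULL,
                          fiber_budget = NULL) {
  if (is.null(fiber_budget)) fiber_budget <- suboptimal_budget(cm, scenario)
  lp <- community_lp(cm, scenario$mu_exp, scenario$total_abundance,
                     fixed_abundances = scenario$fixed_abundances,
                     fiber_budget = fiber_budget,
                     fiber_id = scenario$fiber_id)
  if (is.null(quantities)) {
    quantities <- c(paste0("X.", lp$tags),
                    lp$vars[exchange_var_idx(cm, lp)])
  }
  bad <- setdiff(quantities, lp$vars)
  if (length(bad)) {
    stop("unknown quantity id(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(quantity = quantities, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(quantities)) {
    obj <- numeric(length(lp$vars))
    obj[lp$idx[[quantities[i]]]] <- 1
    lo <- community_solve(lp, obj, maximize = FALSE)
    hi <- community_solve(lp, obj, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("scenario infeasible during FVA of ", quantities[i])
    }
    out$min[i] <- lo$value
    out$max[i] <- hi$value
  }
  out
}

# Verify SteadyCom invariants of a solution; returns TRUE or a character
# vector of violations. Used by tests and the pipeline sanity pass.
check_steadycom_solution <- function(cm, sol, tol = 1e-6) {
  probs <- character(0)
  total <- sum(sol$abundances)
  for (tag in names(cm$members)) {
    m <- cm$members[[tag]]
    v <- sol$member_fluxes[[tag]]
    S <- stoich_matrix(m)
    resid <- max(abs(S %*% v))
    if (resid > tol) probs <- c(probs, paste0(tag, ": mass balance ", resid))
    X <- sol$abundances[[tag]]
    if (X < -tol) probs <- c(probs, paste0(tag, ": negative abundance"))
    bio <- v[[m$biomass_reaction_id]]
    if (abs(bio - sol$mu * X) > tol) {
      probs <- c(probs, paste0(tag, ": biomass coupling off by ",
                               abs(bio - sol$mu * X)))
    }
    viol <- pmax(v - m$reactions$upper_bound * X,
                 m$reactions$lower_bound * X - v)
    if (max(viol) > tol) {
      probs <- c(probs, paste0(tag, ": scaled bound violation ", max(viol)))
    }
  }
  if (length(probs)) probs else TRUE
}
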