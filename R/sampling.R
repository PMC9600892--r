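# Monte Carlo sampling of the suboptimal community flux polytope.
#
# Once the community growth rate is fixed, the SteadyCom constraint system is
# linear, so the feasible set is a convex polytope. It is sampled with an
# artificial-centering hit-and-run chain run in the null space of the
# equality constraints (the polytope is full-dimensional there), retaining
# every `thinning`-th state, with warmup extreme points obtained from LPs
# with randomized objectives.

#' Sampler configuration
#'
#' @param n_samples number of retained sample points.
#' @param thinning keep one point every `thinning` chain steps.
#' @param n_warmup number of warmup extreme points; default
#'   `2 x sampled dimensions`, capped at 2000.
#' @param seed integer RNG seed; identical seed and configuration give a
#'   bit-identical sample matrix.
#' @param tolerance numerical tolerance for chord and feasibility tests.
#' @return a `sampler_config`.
#' @export
sampler_config <- function(n_samples = 200000, thinning = 100,
                           n_warmup = NULL, seed = 1, tolerance = 1e-9) {
  stopifnot(n_samples > 0, thinning >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 thinning = as.integer(thinning),
                 n_warmup = if (!is.null(n_warmup)) as.integer(n_warmup),
                 seed = as.integer(seed), tolerance = tolerance),
            class = "sampler_config")
}

#' Construct a raw polytope
#'
#' Represents `{ x : Aeq x = beq, G x <= h, lb <= x <= ub }` for the sampler
#' and its tests.
#'
#' @param G,h inequality system (may be `NULL`).
#' @param Aeq,beq equality system (may be `NULL`).
#' @param lb,ub box bounds, recycled to the dimension.
#' @param var_names optional variable names.
#' @return a `polytope` object with the box folded into the inequality rows.
#' @export
polytope <- function(G = NULL, h = NULL, Aeq = NULL, beq = NULL,
                     lb = -Inf, ub = Inf, var_names = NULL) {
  n <- if (!is.null(G)) ncol(G) else if (!is.null(Aeq)) ncol(Aeq) else
    if (!is.null(var_names)) length(var_names) else max(length(lb), length(ub))
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  Gfull <- G; hfull <- h
  fin_u <- which(is.finite(ub)); fin_l <- which(is.finite(lb))
  if (length(fin_u)) {
    rows <- matrix(0, length(fin_u), n)
    rows[cbind(seq_along(fin_u), fin_u)] <- 1
    Gfull <- rbind(Gfull, rows); hfull <- c(hfull, ub[fin_u])
  }
  if (length(fin_l)) {
    rows <- matrix(0, length(fin_l), n)
    rows[cbind(seq_along(fin_l), fin_l)] <- -1
    Gfull <- rbind(Gfull, rows); hfull <- c(hfull, -lb[fin_l])
  }
  if (is.null(var_names)) var_names <- paste0("x", seq_len(n))
  structure(list(G = Gfull, h = hfull, Aeq = Aeq, beq = beq,
                 lb = lb, ub = ub, var_names = var_names, n = n),
            class = "polytope")
}

# Community polytope at the scenario's experimental growth rate with the
# suboptimal fiber budget (uptake <= u').
community_polytope <- function(cm, scenario, fiber_budget) {
  lp <- community_lp(cm, scenario$mu_exp, scenario$total_abundance,
                     fixed_abundances = scenario$fixed_abundances,
                     fiber_budget = fiber_budget,
                     fiber_id = scenario$fiber_id)
  p <- polytope(G = lp$Aleq, h = lp$bleq, Aeq = lp$Aeq, beq = lp$beq,
                lb = lp$lb, ub = lp$ub, var_names = lp$vars)
  p$lp <- lp
  p
}

#' Generate warmup points spanning a polytope
#'
#' Solves LPs over the polytope: first the +/- extreme points along each
#' direction of the null-space basis of the equality constraints (the
#' sampled coordinates), then extra randomized objectives if more points are
#' requested; the centroid of the extreme points is appended as an interior
#' start.
#'
#' @param poly a [polytope()].
#' @param n_warmup number of extreme points; default `2 x dimensions`,
#'   capped at 2000.
#' @param seed RNG seed for the randomized objectives.
#' @return matrix of warmup points (rows), in the original coordinates; the
#'   null-space basis and shift are attached as attributes.
#' @export
generate_warmup <- function(poly, n_warmup = NULL, seed = 1) {
  red <- reduce_polytope(poly)
  d <- ncol(red$N)
  if (d == 0L) stop("polytope has no degrees of freedom left to sample")
  if (is.null(n_warmup)) n_warmup <- min(2L * d, 2000L)
  n_warmup <- max(n_warmup, 2L)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  objs <- vector("list", n_warmup)
  k <- 1L
  for (j in seq_len(d)) {
    if (k <= n_warmup) { objs[[k]] <- red$N[, j]; k <- k + 1L }
    if (k <= n_warmup) { objs[[k]] <- -red$N[, j]; k <- k + 1L }
  }
  while (k <= n_warmup) {
    g <- stats::rnorm(d)
    objs[[k]] <- as.numeric(red$N %*% g)
    k <- k + 1L
  }
  pts <- matrix(NA_real_, n_warmup, poly$n)
  for (i in seq_len(n_warmup)) {
    res <- solve_lp(objs[[i]], Aeq = poly$Aeq, beq = poly$beq,
                    Aleq = poly$G, bleq = poly$h,
                    lb = poly$lb, ub = poly$ub, maximize = TRUE)
    if (res$status != "optimal") {
      stop("polytope is infeasible; cannot generate warmup points")
    }
    pts[i, ] <- res$x
  }
  pts <- rbind(pts, colMeans(pts))
  colnames(pts) <- poly$var_names
  attr(pts, "null_basis") <- red$N
  pts
}

# Orthonormal null-space basis of the equality constraints.
reduce_polytope <- function(poly, tol = 1e-9) {
  n <- poly$n
  if (is.null(poly$Aeq) || nrow(poly$Aeq) == 0) {
    return(list(N = diag(n)))
  }
  sv <- svd(poly$Aeq, nu = 0, nv = n)
  rank <- sum(sv$d > tol * max(sv$d, 1))
  if (rank >= n) stop("equality constraints leave no degrees of freedom")
  list(N = sv$v[, (rank + 1):n, drop = FALSE])
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Hit-and-run sampling of a raw polytope
#'
#' @param poly a [polytope()].
#' @param config a [sampler_config()].
#' @param warmup optional warmup matrix from [generate_warmup()]; generated
#'   from `config` when absent.
#' @return matrix (`n_samples` rows) of points in the original coordinates.
#' @export
sample_polytope <- function(poly, config = sampler_config(), warmup = NULL) {
  if (is.null(warmup)) {
    warmup <- generate_warmup(poly, config$n_warmup, seed = config$seed)
  }
  N <- attr(warmup, "null_basis")
  if (is.null(N)) N <- reduce_polytope(poly)$N
  x0 <- colMeans(warmup)  # interior shift
  Z_warm <- (warmup - matrix(x0, nrow(warmup), poly$n, byrow = TRUE)) %*% N
  Gz <- poly$G %*% N
  hz <- poly$h - as.numeric(poly$G %*% x0)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed + 1L)
  Z <- achr_sample_cpp(Gz, hz, Z_warm, config$n_samples, config$thinning,
                       config$tolerance)
  X <- Z %*% t(N) + matrix(x0, nrow(Z), poly$n, byrow = TRUE)
  colnames(X) <- poly$var_names
  X
}

#' Monte Carlo sampling of the community flux polytope
#'
#' Samples the suboptimal community state: growth fixed at the scenario's
#' experimental rate, fiber uptake bounded by the suboptimal budget. The
#' returned matrix holds member abundances and member exchange fluxes
#' (columns) for each retained chain state (rows).
#'
#' @param cm a `community_model`.
#' @param scenario a [scenario_spec()].
#' @param config a [sampler_config()].
#' @param fiber_budget the suboptimal fiber budget u'; computed via
#'   [suboptimal_budget()] when not supplied.
#' @return a `flux_sample_matrix`: numeric matrix with quantity columns,
#'   with the configuration and a scenario fingerprint as attributes.
#' @export
sample_hit_and_run <- function(cm, scenario, config = sampler_config(),
                               fiber_budget = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(config, "sampler_config"))
  if (is.null(fiber_budget)) fiber_budget <- suboptimal_budget(cm, scenario)
  poly <- community_polytope(cm, scenario, fiber_budget)
  X <- sample_polytope(poly, config)
  keep <- c(paste0("X.", names(cm$members)),
            poly$lp$vars[exchange_var_idx(cm, poly$lp)])
  out <- X[, keep, drop = FALSE]
  structure(out,
            class = c("flux_sample_matrix", class(out)),
            config = config,
            scenario_fingerprint = scenario_fingerprint(scenario,
                                                        fiber_budget))
}

scenario_fingerprint <- function(scenario, fiber_budget) {
  paste0("mu_exp=", format(scenario$mu_exp, digits = 12),
         ";fiber=", scenario$fiber_id,
         ";epsilon=", format(scenario$suboptimality_factor, digits = 12),
         ";total=", format(scenario$total_abundance, digits = 12),
         ";budget=", format(fiber_budget, digits = 12))
}

#' Check that sampled points satisfy the polytope constraints
#'
#' @param poly a [polytope()].
#' @param X sample matrix in original coordinates.
#' @return maximum constraint violation across all rows (<= 0 means all
#'   rows strictly feasible).
#' @export
max_constraint_violation <- function(poly, X) {
  viol <- apply(X, 1L, function(x) {
    v <- max(poly$G %*% x - poly$h)
    if (!is.null(poly$Aeq)) {
      v <- max(v, max(abs(poly$Aeq %*% x - poly$beq)))
    }
    v
  })
  max(viol)
}
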