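# Thin LP layer over the package's two-phase simplex (see simplex.R).
#
# The core works on x >= 0 with nonnegative right-hand sides, so problems are
# shifted by their (finite) lower bounds and rows are sign-normalized before
# dispatch. Problem sizes here are small (tens of variables), where a dense
# tableau simplex is fast and, with Bland's rule, robust to the degeneracy
# typical of community flux models.

#' Solve a small dense linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `Aeq x = beq`,
#' `Aleq x <= bleq` and `lb <= x <= ub`. Infinite bounds are replaced by a
#' large finite box (`big`), which must exceed any attainable flux magnitude.
#'
#' @param obj numeric objective coefficients.
#' @param Aeq,beq equality constraints (may be `NULL`).
#' @param Aleq,bleq inequality (<=) constraints (may be `NULL`).
#' @param lb,ub variable bounds, recycled to `length(obj)`.
#' @param maximize logical; maximize instead of minimize.
#' @param big replacement magnitude for infinite bounds.
#' @param n_iter maximum simplex pivots (default scales with problem size).
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (solution in original coordinates) and `value`.
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Aleq = NULL, bleq = NULL,
                     lb = -Inf, ub = Inf, maximize = FALSE, big = 1e4,
                     n_iter = NULL) {
  n <- length(obj)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  lb[!is.finite(lb)] <- -big
  ub[!is.finite(ub)] <- big
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # shift y = x - lb >= 0
  rows_le <- NULL; rhs_le <- numeric(0)
  if (!is.null(Aleq) && nrow(Aleq) > 0) {
    rows_le <- Aleq
    rhs_le <- as.numeric(bleq) - as.numeric(Aleq %*% lb)
  }
  # upper bounds as y <= ub - lb
  span <- ub - lb
  bound_rows <- diag(n)
  rows_le <- rbind(rows_le, bound_rows)
  rhs_le <- c(rhs_le, span)

  rhs_eq <- numeric(0); rows_eq <- NULL
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    rows_eq <- Aeq
    rhs_eq <- as.numeric(beq) - as.numeric(Aeq %*% lb)
    neg <- rhs_eq < 0
    if (any(neg)) {
      rows_eq[neg, ] <- -rows_eq[neg, , drop = FALSE]
      rhs_eq[neg] <- -rhs_eq[neg]
    }
  }
  # <= rows with negative rhs become >= rows after negation
  neg <- rhs_le < 0
  A1 <- rows_le[!neg, , drop = FALSE]; b1 <- rhs_le[!neg]
  A2 <- -rows_le[neg, , drop = FALSE]; b2 <- -rhs_le[neg]

  res <- simplex_solve(
    obj,
    A1 = if (nrow(A1)) A1 else NULL, b1 = b1,
    A2 = if (nrow(A2)) A2 else NULL, b2 = b2,
    A3 = rows_eq, b3 = rhs_eq,
    maximize = maximize, max_iter = n_iter)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, value = NA_real_))
  }
  x <- as.numeric(res$x) + lb
  # defensive residual check: a near-degenerate phase 1 can accept a point
  # that is not actually feasible; treat such points as infeasible
  viol <- max(0, lb - x, x - ub)
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    viol <- max(viol, abs(Aeq %*% x - beq))
  }
  if (!is.null(Aleq) && nrow(Aleq) > 0) {
    viol <- max(viol, Aleq %*% x - bleq)
  }
  if (viol > 1e-6 * max(1, max(abs(x)))) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  names(x) <- names(obj)
  list(status = "optimal", x = x, value = sum(obj * x))
}

#' Check feasibility of a polyhedron `Aeq x = beq`, `Aleq x <= bleq`, box bounds
#' @return list(feasible = logical, x = witness or NULL)
#' @keywords internal
lp_feasible <- function(Aeq = NULL, beq = NULL, Aleq = NULL, bleq = NULL,
                        lb = -Inf, ub = Inf, big = 1e4) {
  n <- if (!is.null(Aeq)) ncol(Aeq) else ncol(Aleq)
  res <- solve_lp(numeric(n), Aeq, beq, Aleq, bleq, lb, ub, big = big)
  list(feasible = res$status == "optimal", x = res$x)
}
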