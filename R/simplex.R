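# Dense two-phase primal simplex with Bland's rule.
#
# Operates on the standard form used by solve_lp(): variables y >= 0,
# A1 y <= b1, A2 y >= b2, A3 y = b3 with all right-hand sides nonnegative.
# Slack variables provide the initial basis for the <= rows; >= and =
# rows get artificial variables minimized in phase 1. Bland's smallest-index
# rule guarantees termination on the highly degenerate systems that
# community flux models produce (many bound rows active at once).

simplex_solve <- function(obj, A1 = NULL, b1 = numeric(0),
                          A2 = NULL, b2 = numeric(0),
                          A3 = NULL, b3 = numeric(0),
                          maximize = FALSE, tol = 1e-9, max_iter = NULL) {
  n <- length(obj)
  m1 <- length(b1); m2 <- length(b2); m3 <- length(b3)
  m <- m1 + m2 + m3
  if (any(c(b1, b2, b3) < 0)) stop("right-hand sides must be nonnegative")
  if (maximize) obj <- -obj

  zero <- function(r, c) matrix(0, r, c)
  base <- rbind(
    if (m1) cbind(A1, diag(m1), zero(m1, m2)) else NULL,
    if (m2) cbind(A2, zero(m2, m1), -diag(m2)) else NULL,
    if (m3) cbind(A3, zero(m3, m1), zero(m3, m2)) else NULL)
  n_real <- n + m1 + m2
  n_art <- m2 + m3
  A <- if (n_art) {
    cbind(base, rbind(zero(m1, n_art), diag(n_art)))
  } else {
    base
  }
  b <- c(b1, b2, b3)
  nc <- ncol(A)
  basis <- c(if (m1) n + seq_len(m1),
             if (n_art) n_real + seq_len(n_art))

  if (is.null(max_iter)) max_iter <- 2000L + 50L * (m + nc)
  T <- cbind(A, b)
  iter <- 0L

  pivot <- function(p, q) {
    colq <- T[, q]
    prow <- T[p, ] / colq[p]
    T <<- T - outer(colq, prow)
    T[p, ] <<- prow
    basis[p] <<- q
  }

  run_phase <- function(cost, allowed) {
    repeat {
      iter <<- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit exceeded")
      red <- cost - as.numeric(cost[basis] %*% T[, seq_len(nc), drop = FALSE])
      cand <- which(allowed & red < -tol)
      if (!length(cand)) return("optimal")
      q <- cand[1L]  # Bland: smallest index
      colq <- T[, q]
      rows <- which(colq > tol)
      if (!length(rows)) return("unbounded")
      ratio <- T[rows, nc + 1L] / colq[rows]
      best <- rows[ratio <= min(ratio) + 1e-12]
      p <- best[which.min(basis[best])]  # Bland tie-break
      pivot(p, q)
    }
  }

  art_cols <- if (n_art) n_real + seq_len(n_art) else integer(0)
  if (n_art) {
    cost1 <- c(numeric(n_real), rep(1, n_art))
    st <- run_phase(cost1, allowed = rep(TRUE, nc))
    feas_val <- sum(cost1[basis] * T[, nc + 1L])
    if (st != "optimal" || feas_val > 1e-7) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # drive remaining artificials out of the basis, or drop redundant rows;
    # clamp their (tiny) values to zero first so a pivot on a negative entry
    # cannot push a basic variable below zero
    drop_rows <- integer(0)
    for (p in which(basis %in% art_cols)) {
      T[p, nc + 1L] <- 0
      entry <- which(abs(T[p, seq_len(n_real)]) > tol)
      if (length(entry)) {
        pivot(p, entry[1L])
      } else {
        drop_rows <- c(drop_rows, p)
      }
    }
    if (length(drop_rows)) {
      T <- T[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
  }

  cost2 <- c(obj, numeric(m1 + m2), rep(0, n_art))
  allowed <- rep(TRUE, nc)
  allowed[art_cols] <- FALSE
  st <- run_phase(cost2, allowed)
  if (st == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  x_full <- numeric(nc)
  x_full[basis] <- T[, nc + 1L]
  x <- x_full[seq_len(n)]
  val <- sum(obj * x)
  list(status = "optimal", x = x, value = if (maximize) -val else val)
}
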