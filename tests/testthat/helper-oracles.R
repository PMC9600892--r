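# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the growth-rate oracle scans a fine mu grid instead
# of bisecting, and the FVA oracle enumerates polytope vertices instead of
# running per-quantity LPs.

# Largest feasible community growth rate located by scanning a fine mu grid.
grid_mu_oracle <- function(cm, mu_hi, step = 1e-4, total_abundance = 1) {
  grid <- seq(0, mu_hi, by = step)
  feasible <- vapply(grid, function(mu) {
    lp <- steadycross:::community_lp(cm, mu, total_abundance)
    steadycross:::lp_feasible(lp$Aeq, lp$beq, lp$Aleq, lp$bleq,
                              lp$lb, lp$ub)$feasible
  }, logical(1))
  if (!any(feasible)) return(NA_real_)
  max(grid[feasible])
}

# Vertex enumeration over a low-dimensional polytope: parameterize by the
# null space of the equalities, solve every d-subset of active inequality
# rows, keep feasible intersections. Returns vertices in the original
# coordinates (rows).
enumerate_vertices <- function(poly, tol = 1e-7) {
  red <- steadycross:::reduce_polytope(poly)
  N <- red$N
  d <- ncol(N)
  stopifnot(d <= 6)
  # shift: any feasible point
  x0 <- steadycross:::solve_lp(numeric(poly$n), Aeq = poly$Aeq,
                               beq = poly$beq, Aleq = poly$G, bleq = poly$h,
                               lb = poly$lb, ub = poly$ub)$x
  G <- poly$G %*% N
  h <- poly$h - as.numeric(poly$G %*% x0)
  m <- nrow(G)
  verts <- list()
  for (rows in utils::combn(m, d, simplify = FALSE)) {
    A <- G[rows, , drop = FALSE]
    if (abs(det(A)) < tol) next
    z <- solve(A, h[rows])
    if (all(G %*% z <= h + tol)) {
      verts[[length(verts) + 1L]] <- as.numeric(x0 + N %*% z)
    }
  }
  out <- unique(do.call(rbind, verts))
  colnames(out) <- poly$var_names
  out
}

# FVA by vertex enumeration: min/max of each quantity over the vertex set.
vertex_fva_oracle <- function(poly, quantities) {
  V <- enumerate_vertices(poly)
  data.frame(quantity = quantities,
             min = vapply(quantities, function(q) min(V[, q]), numeric(1)),
             max = vapply(quantities, function(q) max(V[, q]), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
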