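test_that("warmup includes both endpoints of an interval polytope", {
  # 1-dim interval [2, 7]
  p <- polytope(lb = 2, ub = 7, var_names = "x")
  w <- generate_warmup(p, seed = 1)
  expect_true(any(abs(w[, "x"] - 2) < 1e-9))
  expect_true(any(abs(w[, "x"] - 7) < 1e-9))
})

test_that("warmup points are feasible and their centroid is interior", {
  # 3-dim box [0,1]^3
  p <- polytope(lb = 0, ub = 1, var_names = paste0("b", 1:3))
  w <- generate_warmup(p, seed = 2)
  expect_lte(max_constraint_violation(p, w), 1e-9)
  centroid <- w[nrow(w), ]
  expect_true(all(centroid > 1e-6 & centroid < 1 - 1e-6))
})

test_that("unit-box sample means are within 3 Monte Carlo standard errors", {
  p <- polytope(lb = 0, ub = 1, var_names = paste0("u", 1:3))
  n <- 10000
  X <- sample_polytope(p, sampler_config(n_samples = n, thinning = 5,
                                         seed = 7))
  # thinned chain still autocorrelated; use a conservative effective n
  se <- sqrt(1 / 12) / sqrt(n / 10)
  for (j in seq_len(ncol(X))) {
    expect_lt(abs(mean(X[, j]) - 0.5), 3 * se)
  }
  expect_lte(max_constraint_violation(p, X), 1e-9)
})

test_that("identical seed and config give bit-identical matrices", {
  toy <- make_toy_degrader_butyrogen()
  cfg <- sampler_config(n_samples = 500, thinning = 20, seed = 42)
  b <- suboptimal_budget(toy$community, toy$scenario)
  s1 <- sample_hit_and_run(toy$community, toy$scenario, cfg, fiber_budget = b)
  s2 <- sample_hit_and_run(toy$community, toy$scenario, cfg, fiber_budget = b)
  expect_identical(unclass(s1), unclass(s2))
})

test_that("different seeds agree within Monte Carlo error on column means", {
  toy <- make_toy_degrader_butyrogen()
  b <- suboptimal_budget(toy$community, toy$scenario)
  s1 <- sample_hit_and_run(toy$community, toy$scenario,
                           sampler_config(n_samples = 4000, thinning = 10,
                                          seed = 1), fiber_budget = b)
  s2 <- sample_hit_and_run(toy$community, toy$scenario,
                           sampler_config(n_samples = 4000, thinning = 10,
                                          seed = 2), fiber_budget = b)
  for (q in colnames(s1)) {
    spread <- diff(range(s1[, q]))
    if (spread < 1e-12) next
    expect_lt(abs(mean(s1[, q]) - mean(s2[, q])), 0.2 * spread,
              label = paste("seed agreement for", q))
  }
})

test_that("split halves of a chain have consistent column means", {
  toy <- make_toy_degrader_butyrogen()
  b <- suboptimal_budget(toy$community, toy$scenario)
  s <- sample_hit_and_run(toy$community, toy$scenario,
                          sampler_config(n_samples = 4000, thinning = 10,
                                         seed = 3), fiber_budget = b)
  half <- nrow(s) %/% 2
  for (q in colnames(s)) {
    a <- s[seq_len(half), q]
    bcol <- s[half + seq_len(half), q]
    pooled_se <- sqrt(stats::var(a) / (half / 10) +
                      stats::var(bcol) / (half / 10))
    if (pooled_se < 1e-12) next
    expect_lt(abs(mean(a) - mean(bcol)), 3 * pooled_se,
              label = paste("split-half for", q))
  }
})

test_that("every retained community sample satisfies all constraints", {
  toy <- make_toy_degrader_butyrogen()
  b <- suboptimal_budget(toy$community, toy$scenario)
  poly <- steadycross:::community_polytope(toy$community, toy$scenario, b)
  X <- sample_polytope(poly, sampler_config(n_samples = 300, thinning = 20,
                                            seed = 4))
  expect_lte(max_constraint_violation(poly, X), 1e-6)
  # biomass coupling and abundance sum, spot-checked explicitly
  expect_equal(unname(X[, "degrader.BIO_D"]),
               unname(0.35 * X[, "X.degrader"]), tolerance = 1e-8)
  expect_equal(unname(X[, "X.degrader"] + X[, "X.butyrogen"]),
               rep(1, nrow(X)), tolerance = 1e-8)
})

test_that("the sampler records its configuration and scenario fingerprint", {
  cfg <- sampler_config()  # reference configuration
  expect_equal(cfg$n_samples, 200000L)
  expect_equal(cfg$thinning, 100L)
  toy <- make_toy_degrader_butyrogen()
  b <- suboptimal_budget(toy$community, toy$scenario)
  s <- sample_hit_and_run(toy$community, toy$scenario,
                          sampler_config(n_samples = 100, thinning = 10,
                                         seed = 1), fiber_budget = b)
  expect_s3_class(attr(s, "config"), "sampler_config")
  expect_match(attr(s, "scenario_fingerprint"), "mu_exp=0.35")
  expect_equal(nrow(s), 100)
})

test_that("a zero-dimensional polytope is rejected with guidance", {
  p <- polytope(lb = c(1, 2), ub = c(1, 2), var_names = c("a", "b"))
  expect_error(sample_polytope(p, sampler_config(n_samples = 10, seed = 1)),
               "width below tolerance|degrees of freedom")
})

test_that("sampler configuration validates its inputs", {
  expect_error(sampler_config(n_samples = 0), "n_samples")
  expect_error(sampler_config(thinning = 0), "thinning")
})
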