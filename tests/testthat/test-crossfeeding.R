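make_sample_matrix <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

test_that("classification follows the median sign and significance rule", {
  set.seed(10)
  m <- make_sample_matrix(
    up = rep(1, 50),                      # all positive -> produced
    down = rep(-1, 50),                   # all negative -> consumed
    sym = c(seq(-1, 1, length.out = 50)), # symmetric -> indeterminate
    zero = rep(0, 50))                    # constant zero -> flagged
  rep <- classify_exchanges(m, alpha = 0.01)
  cl <- rep$classification
  expect_identical(cl$classification[cl$quantity == "up"], "produced")
  expect_lt(cl$p_value[cl$quantity == "up"], 1e-6)
  expect_identical(cl$classification[cl$quantity == "down"], "consumed")
  expect_identical(cl$classification[cl$quantity == "sym"], "indeterminate")
  expect_identical(cl$classification[cl$quantity == "zero"], "indeterminate")
  expect_identical(cl$p_value[cl$quantity == "zero"], 1)
  expect_true(cl$flagged[cl$quantity == "zero"])
  expect_false(any(cl$flagged[cl$quantity != "zero"]))
})

test_that("classification is monotone under positive shifts", {
  set.seed(11)
  x <- stats::rnorm(200)
  for (shift in c(0, 0.5, 2, 10)) {
    m <- make_sample_matrix(a = x + shift, b = stats::rnorm(200))
    cl <- classify_exchanges(m)$classification
    got <- cl$classification[cl$quantity == "a"]
    # adding a positive constant can never turn produced into consumed
    if (shift >= 2) expect_identical(got, "produced")
    expect_false(got == "consumed" && shift > 0 &&
                   stats::median(x) + shift > 0)
  }
})

test_that("correlation is affine-invariant and flips sign under negation", {
  set.seed(12)
  x <- stats::rnorm(100); y <- x + stats::rnorm(100, sd = 0.3)
  m1 <- make_sample_matrix(x = x, y = y)
  m2 <- make_sample_matrix(x = 10 * x + 3, y = y)
  m3 <- make_sample_matrix(x = -x, y = y)
  c1 <- exchange_correlation(m1)["x", "y"]
  expect_equal(exchange_correlation(m2)["x", "y"], c1, tolerance = 1e-12)
  expect_equal(exchange_correlation(m3)["x", "y"], -c1, tolerance = 1e-12)
  # exact -1 for a column and its negation
  m4 <- make_sample_matrix(x = x, nx = -x)
  expect_identical(exchange_correlation(m4)["x", "nx"], -1)
})

test_that("balance-coupled exchange pairs are perfectly anticorrelated", {
  cp <- make_coupled_pair()
  s <- sample_hit_and_run(cp$community, cp$scenario,
                          sampler_config(n_samples = 400, thinning = 10,
                                         seed = 6), fiber_budget = 1e6)
  cc <- exchange_correlation(s)
  expect_equal(cc["producer.EX_shared", "consumer.EX_shared"], -1,
               tolerance = 1e-9)
  # matrix structure: symmetric, unit diagonal, entries within [-1, 1]
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, nrow(cc)))
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
})

test_that("constant columns are excluded from the correlation matrix", {
  m <- make_sample_matrix(a = stats::rnorm(50), flat = rep(2, 50))
  cc <- exchange_correlation(m)
  expect_false("flat" %in% colnames(cc))
  expect_identical(attr(cc, "excluded"), "flat")
  expect_error(exchange_correlation(m[1:2, , drop = FALSE]), "3 samples")
})

test_that("density summaries agree with the classification medians", {
  toy <- make_toy_degrader_butyrogen()
  s <- sample_hit_and_run(toy$community, toy$scenario,
                          sampler_config(n_samples = 500, thinning = 10,
                                         seed = 2))
  dens <- summarize_densities(s)
  cl <- classify_exchanges(s)$classification
  for (q in colnames(s)) {
    expect_identical(dens[[q]]$median, cl$median[cl$quantity == q])
    expect_equal(sum(dens[[q]]$counts), nrow(s))
  }
})

test_that("density summaries handle constant and uniform columns", {
  flat <- make_sample_matrix(c0 = rep(3, 100))
  d <- summarize_densities(flat)
  expect_equal(length(d$c0$counts), 1)
  expect_equal(d$c0$counts, 100)

  p <- polytope(lb = 0, ub = 1, var_names = "u")
  X <- sample_polytope(p, sampler_config(n_samples = 5000, thinning = 5,
                                         seed = 9))
  d <- summarize_densities(X)$u
  # chi-square flatness sanity check against the uniform expectation
  widths <- diff(d$breaks)
  expected <- 5000 * widths / sum(widths)
  chi2 <- sum((d$counts - expected)^2 / expected)
  dof <- length(d$counts) - 1
  expect_lt(chi2, dof + 6 * sqrt(2 * dof))
})

test_that("the toy community reproduces the expected cross-feeding pattern", {
  toy <- make_toy_degrader_butyrogen()
  s <- sample_hit_and_run(toy$community, toy$scenario,
                          sampler_config(n_samples = 2000, thinning = 20,
                                         seed = 13))
  rep <- classify_exchanges(s, alpha = 0.01)
  cl <- function(q) rep$classification$classification[
    rep$classification$quantity == q]
  expect_identical(cl("degrader.EX_lac"), "produced")
  expect_identical(cl("butyrogen.EX_lac"), "consumed")
  expect_identical(cl("degrader.EX_suc"), "produced")
  expect_identical(cl("butyrogen.EX_but"), "produced")
  expect_identical(cl("degrader.EX_fiber"), "consumed")
  # lactate has no community sink: exchanges couple at exactly -1
  expect_equal(rep$correlation["degrader.EX_lac", "butyrogen.EX_lac"], -1,
               tolerance = 1e-9)
})
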