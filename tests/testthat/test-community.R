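test_that("a single-member community reduces to scaled single-organism FBA", {
  # yield 0.1 biomass per substrate, uptake cap 10 -> mu* = 1.0
  net <- make_linear_chain(uptake_cap = 10, yield = 0.1)
  med <- medium(uptake_bounds = c(EX_s_e = 1000), carbon_source_id = "EX_s_e")
  cm <- assemble_community(list(solo = net), med)
  sol <- max_community_growth(cm)
  expect_equal(sol$mu, 1.0, tolerance = 2e-6)
  expect_equal(unname(sol$abundances[["solo"]]), 1, tolerance = 1e-6)
  check <- steadycross:::check_steadycom_solution(cm, sol)
  expect_true(isTRUE(check))
})

test_that("members sharing a metabolite are linked by one pool balance row", {
  toy <- make_toy_degrader_butyrogen()
  cm <- toy$community
  lp <- steadycross:::community_lp(cm, 0.3)
  # the pool row for lactate couples both members' lactate exchanges and the
  # community exchange, all with coefficient +-1
  i_lac <- which(cm$pool_mets == "lactate_e")
  row_idx <- sum(vapply(cm$members, function(m) nrow(m$metabolites),
                        integer(1))) + i_lac
  row <- lp$Aeq[row_idx, ]
  nz <- which(row != 0)
  expect_setequal(lp$vars[nz], c("degrader.EX_lac", "butyrogen.EX_lac",
                                 "EX.lactate_e"))
})

test_that("a pool metabolite without community exchange forces producer flux = consumer flux", {
  cp <- make_coupled_pair()
  s <- sample_hit_and_run(cp$community, cp$scenario,
                          sampler_config(n_samples = 200, thinning = 10,
                                         seed = 5),
                          fiber_budget = 1e6)
  expect_equal(unname(s[, "producer.EX_shared"]),
               unname(-s[, "consumer.EX_shared"]), tolerance = 1e-9)
})

test_that("bisection agrees with the fine-grid feasibility oracle", {
  fixtures <- list(
    make_toy_degrader_butyrogen(),
    make_toy_degrader_butyrogen(toy_community_params(
      average_dp = 5, fiber_uptake_cap = 1, lactate_per_biomass = 2,
      acetate_per_biomass = 1, lactate_per_biomass_b = 2,
      acetate_per_biomass_b = 3)))
  for (fx in fixtures) {
    sol <- max_community_growth(fx$community)
    expect_equal(sol$mu, fx$answers$mu_star, tolerance = 2e-6,
                 label = "bisection vs closed form")
    oracle <- grid_mu_oracle(fx$community, mu_hi = fx$answers$mu_star * 1.2,
                             step = 1e-3)
    expect_lte(abs(sol$mu - oracle), 1e-3 + 2e-6)
  }
})

test_that("min_fiber_uptake matches the closed form and satisfies duality", {
  toy <- make_toy_degrader_butyrogen()
  cm <- toy$community
  for (mu in c(0.2, 0.35, 0.45)) {
    sol <- min_fiber_uptake(cm, mu, "fiber_id" = "fiber_e")
    expect_equal(sol$fiber_uptake, toy$answers$u_min_of_mu(mu),
                 tolerance = 1e-6)
    expect_true(isTRUE(steadycross:::check_steadycom_solution(cm, sol)))
    # duality: max growth under that fiber budget returns mu
    dual <- max_community_growth(cm, fiber_id = "fiber_e",
                                 fiber_budget = sol$fiber_uptake)
    expect_equal(dual$mu, mu, tolerance = 1e-5)
  }
})

test_that("infeasible growth reports the maximum feasible rate", {
  toy <- make_toy_degrader_butyrogen()
  expect_error(min_fiber_uptake(toy$community, 2, "fiber_e"),
               "maximum feasible")
})

test_that("max growth is non-decreasing in the fiber uptake budget", {
  toy <- make_toy_degrader_butyrogen()
  mus <- vapply(c(0.01, 0.02, 0.04, 0.08), function(u) {
    max_community_growth(toy$community, fiber_id = "fiber_e",
                         fiber_budget = u)$mu
  }, numeric(1))
  expect_true(all(diff(mus) >= -1e-9))
})

test_that("suboptimal budget scales linearly in the yield-chain community", {
  toy <- make_toy_degrader_butyrogen()
  scen0 <- toy$scenario
  scen0$suboptimality_factor <- 0
  u0 <- suboptimal_budget(toy$community, scen0)
  expect_equal(u0, toy$answers$u_min, tolerance = 1e-6)
  u <- suboptimal_budget(toy$community, toy$scenario)
  expect_equal(u, (1 + toy$scenario$suboptimality_factor) * u0,
               tolerance = 1e-6)
})

test_that("FVA agrees with the vertex-enumeration oracle on the coupled pair", {
  cp <- make_coupled_pair()
  poly <- steadycross:::community_polytope(cp$community, cp$scenario, 1e6)
  q <- cp$answers$coupled_exchange
  fva <- community_fva(cp$community, cp$scenario, quantities = q,
                       fiber_budget = 1e6)
  oracle <- vertex_fva_oracle(poly, q)
  expect_equal(fva$min, oracle$min, tolerance = 1e-6)
  expect_equal(fva$max, oracle$max, tolerance = 1e-6)
  expect_equal(fva$min, c(0, -cp$answers$shared_range[2]), tolerance = 1e-9)
  expect_equal(fva$max, c(cp$answers$shared_range[2], 0), tolerance = 1e-9)
})

test_that("FVA bounds match the analytic abundance ranges and contain samples", {
  toy <- make_toy_degrader_butyrogen()
  budget <- suboptimal_budget(toy$community, toy$scenario)
  fva <- community_fva(toy$community, toy$scenario, fiber_budget = budget)
  rng <- function(q) unlist(fva[fva$quantity == q, c("min", "max")],
                            use.names = FALSE)
  expect_equal(rng("X.degrader"), toy$answers$degrader_abundance_range,
               tolerance = 1e-6)
  expect_equal(rng("X.butyrogen"), toy$answers$butyrogen_abundance_range,
               tolerance = 1e-6)
  expect_equal(rng("degrader.EX_lac"), toy$answers$degrader_lactate_range,
               tolerance = 1e-6)
  # every sampled point lies inside its FVA range (tolerance-padded)
  s <- sample_hit_and_run(toy$community, toy$scenario,
                          sampler_config(n_samples = 100, thinning = 20,
                                         seed = 8),
                          fiber_budget = budget)
  for (q in fva$quantity) {
    expect_gte(min(s[, q]), rng(q)[1] - 1e-6)
    expect_lte(max(s[, q]), rng(q)[2] + 1e-6)
  }
})

test_that("witness solutions satisfy all SteadyCom invariants", {
  toy <- make_toy_degrader_butyrogen()
  sols <- list(
    max_community_growth(toy$community, fiber_id = "fiber_e"),
    min_fiber_uptake(toy$community, 0.35, "fiber_e"))
  for (sol in sols) {
    expect_true(isTRUE(steadycross:::check_steadycom_solution(
      toy$community, sol)))
    expect_equal(sum(sol$abundances), 1, tolerance = 1e-6)
  }
})

test_that("community growth is unbounded without a limiting uptake", {
  net <- make_linear_chain(uptake_cap = 1000, yield = 100)
  med <- medium(uptake_bounds = c(EX_s_e = 1000), carbon_source_id = "EX_s_e")
  cm <- assemble_community(list(solo = net), med)
  expect_error(max_community_growth(cm, mu_max = 10), "not limited")
})
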