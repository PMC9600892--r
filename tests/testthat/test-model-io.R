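test_that("JSON round trip is a byte-stable fixed point", {
  toy <- make_toy_degrader_butyrogen()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(toy$degrader, p1, "json")
  n1 <- read_model(p1, "json")
  write_model(n1, p2, "json")
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(stoich_matrix(n1), stoich_matrix(toy$degrader))
  expect_equal(n1$reactions, toy$degrader$reactions)
  expect_equal(nrow(n1$reactions), 6)
  expect_equal(sum(n1$reactions$is_exchange), 4)
})

test_that("malformed or incomplete model files raise informative errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", p)
  expect_error(read_model(p, "json"), "malformed")
  writeLines('{"model_id": "m", "metabolites": [], "reactions": []}', p)
  expect_error(read_model(p, "json"), "biomass")
  expect_error(read_model("/nonexistent/model.json"), "does not exist")
})

test_that("SBML-FBC round trip preserves content", {
  toy <- make_toy_degrader_butyrogen()
  for (net in list(toy$degrader, toy$butyrogen)) {
    p <- withr::local_tempfile(fileext = ".xml")
    write_model(net, p, "sbml_fbc")
    n2 <- read_model(p, "sbml_fbc")
    S0 <- stoich_matrix(net)
    S2 <- stoich_matrix(n2)
    expect_identical(S2[rownames(S0), colnames(S0)], S0)
    expect_equal(n2$reactions$lower_bound, net$reactions$lower_bound)
    expect_equal(n2$reactions$upper_bound, net$reactions$upper_bound)
    expect_identical(n2$biomass_reaction_id, net$biomass_reaction_id)
    expect_identical(sort(n2$reactions$id[n2$reactions$is_exchange]),
                     sort(net$reactions$id[net$reactions$is_exchange]))
    expect_identical(
      n2$metabolites$formula[match(net$metabolites$id, n2$metabolites$id)],
      net$metabolites$formula)
  }
})

test_that("an independent SBML parser reads the exported model identically", {
  toy <- make_toy_degrader_butyrogen()
  p <- withr::local_tempfile(fileext = ".xml")
  write_model(toy$degrader, p, "sbml_fbc")
  script <- paste(
    "import sys, json, cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "out = {r.id: {k.id: v for k, v in r.metabolites.items()}",
    "       for r in m.reactions}",
    "bounds = {r.id: [r.lower_bound, r.upper_bound] for r in m.reactions}",
    "print(json.dumps({'stoich': out, 'bounds': bounds}))",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", c(sf, p), stdout = TRUE, stderr = FALSE)
  parsed <- jsonlite::fromJSON(out[length(out)])
  for (rid in toy$degrader$reactions$id) {
    s <- toy$degrader$stoichiometry[[rid]]
    got <- unlist(parsed$stoich[[rid]])
    expect_equal(got[names(s)], s, tolerance = 1e-12,
                 label = paste("cobra stoichiometry of", rid))
    i <- match(rid, toy$degrader$reactions$id)
    expect_equal(unlist(parsed$bounds[[rid]]),
                 c(toy$degrader$reactions$lower_bound[i],
                   toy$degrader$reactions$upper_bound[i]),
                 tolerance = 1e-12, ignore_attr = TRUE,
                 label = paste("cobra bounds of", rid))
  }
})

test_that("network invariants are enforced at construction", {
  toy <- make_toy_degrader_butyrogen()
  net <- toy$degrader
  bad <- net
  bad$stoichiometry$HYD <- c(fiber_e = -1, ghost_met = 5)
  expect_error(validate_network(bad), "ghost_met")
  bad <- net
  bad$reactions$lower_bound[2] <- 10
  bad$reactions$upper_bound[2] <- -10
  expect_error(validate_network(bad), "lower_bound")
  bad <- net
  bad$stoichiometry$EX_fiber <- c(fiber_e = -1, monomer_c = 1)
  expect_error(validate_network(bad), "exactly one metabolite")
})
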