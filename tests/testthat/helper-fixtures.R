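# Small fixtures built in code at test time.

# Single-organism linear chain: uptake (cap 10) -> substrate -> biomass with
# yield 0.1 per unit substrate, so optimal growth = 1.0 exactly.
make_linear_chain <- function(uptake_cap = 10, yield = 0.1) {
  metabolic_network(
    "chain",
    metabolites = data.frame(
      id = c("s_e", "x_c"), name = c("substrate", "precursor"),
      formula = c("C6H12O6", NA), compartment = c("e", "c"),
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_s", "T_s", "BIO"),
      name = c("substrate exchange", "transport", "biomass"),
      lower_bound = c(-uptake_cap, 0, 0), upper_bound = c(1000, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE),
    stoichiometry = list(EX_s = c(s_e = -1),
                         T_s = c(s_e = -1, x_c = 1),
                         BIO = c(x_c = -1 / yield)),
    biomass_reaction_id = "BIO")
}

chain_medium <- function(bound = 10) {
  medium(uptake_bounds = c(EX_s = bound), carbon_source_id = "EX_s")
}

# Toy model with two carbon exchanges and one mineral exchange, for the
# medium closure rules.
make_two_sugar_model <- function() {
  metabolic_network(
    "two_sugar",
    metabolites = data.frame(
      id = c("glc_e", "inu_e", "min_e", "x_c"),
      name = c("glucose", "fructan", "mineral", "precursor"),
      formula = c("C6H12O6", "C150", NA, NA),
      compartment = c("e", "e", "e", "c"), stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_glc", "EX_inu", "EX_min", "CAT_glc", "CAT_inu", "T_min",
             "BIO"),
      name = c("glucose exchange", "fructan exchange", "mineral exchange",
               "glucose catabolism", "fructan catabolism",
               "mineral transport", "biomass"),
      lower_bound = c(-10, -10, -10, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000, 1000),
      is_exchange = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    stoichiometry = list(
      EX_glc = c(glc_e = -1), EX_inu = c(inu_e = -1),
      EX_min = c(min_e = -1),
      CAT_glc = c(glc_e = -1, x_c = 1), CAT_inu = c(inu_e = -1, x_c = 25),
      T_min = c(min_e = -1),
      BIO = c(x_c = -10)),
    biomass_reaction_id = "BIO")
}

write_toy_scenario <- function(dir, n_samples = 2000, thinning = 50,
                               params = toy_community_params()) {
  toy <- make_toy_degrader_butyrogen(params)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model(toy$degrader, file.path(dir, "degrader.json"), "json")
  write_model(toy$butyrogen, file.path(dir, "butyrogen.json"), "json")
  yaml::write_yaml(list(carbon_source_id = "EX_fiber_e",
                        uptake_bounds = list(EX_fiber_e = 10),
                        excess_value = 1000,
                        export_bounds = list(EX_lactate_e = 0)),
                   file.path(dir, "medium.yaml"))
  cfg <- list(
    models = list(degrader = list(path = "degrader.json"),
                  butyrogen = list(path = "butyrogen.json")),
    medium = "medium.yaml",
    scenario = list(mu_exp = params$mu_exp, fiber_id = "fiber_e",
                    suboptimality_factor = params$suboptimality_factor),
    sampler = list(n_samples = n_samples, thinning = thinning),
    alpha = 0.01)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  list(toy = toy, config = file.path(dir, "config.yaml"))
}
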