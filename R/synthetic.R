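# Synthetic fixtures with analytically known answers.
#
# The central generator emulates the topology of a fiber-degrading /
# butyrate-producing gut consortium: a degrader hydrolyzes a fiber polymer
# (average DP monomer units per chain), grows on the monomer, and secretes
# lactate, succinate and acetate in fixed proportion to growth
# (mixed-acid fermentation); a butyrogen grows on the degrader's lactate and
# acetate and vents surplus lactate carbon as butyrate (2 lactate ->
# butyrate + acetate, carbon-exact). Lactate cannot leave the community
# environment, so all lactate carbon flows through the butyrogen — the
# linear yield chain that makes every community optimum available in closed
# form (see the answer sheet fields below).

#' Parameters of the synthetic degrader/butyrogen community
#'
#' Defaults emulate growth on an inulin-like fructan: DP 25 chains of a
#' 6-carbon monomer, an experimentally observed community growth rate of
#' 0.35 h^-1, and a 5% suboptimality factor.
#'
#' @param average_dp monomer units per fiber chain.
#' @param carbon_per_monomer carbon atoms per monomer.
#' @param monomer_per_biomass mmol monomer consumed per unit degrader
#'   biomass (inverse growth yield).
#' @param lactate_per_biomass,succinate_per_biomass,acetate_per_biomass
#'   mmol of each acid secreted per unit degrader biomass.
#' @param fiber_uptake_cap degrader fiber uptake capacity (mmol/gDW/h).
#' @param lactate_per_biomass_b,acetate_per_biomass_b mmol lactate (resp.
#'   acetate) consumed per unit butyrogen biomass on each growth route.
#' @param butyrate_cap butyrogen butyrate-production capacity (mmol/gDW/h).
#' @param lactate_uptake_cap,acetate_uptake_cap butyrogen uptake capacities.
#' @param mu_exp experimental community growth rate (h^-1).
#' @param suboptimality_factor fiber-budget relaxation factor.
#' @param seed RNG seed recorded with the fixture.
#' @return a `toy_community_params` object.
#' @export
toy_community_params <- function(average_dp = 25, carbon_per_monomer = 6,
                                 monomer_per_biomass = 10,
                                 lactate_per_biomass = 4,
                                 succinate_per_biomass = 1,
                                 acetate_per_biomass = 2,
                                 fiber_uptake_cap = 0.2,
                                 lactate_per_biomass_b = 3,
                                 acetate_per_biomass_b = 6,
                                 butyrate_cap = 10,
                                 lactate_uptake_cap = 20,
                                 acetate_uptake_cap = 20,
                                 mu_exp = 0.35,
                                 suboptimality_factor = 0.05,
                                 seed = 1) {
  p <- structure(as.list(environment()), class = "toy_community_params")
  if (any(unlist(p[c("monomer_per_biomass", "lactate_per_biomass",
                     "succinate_per_biomass", "acetate_per_biomass",
                     "lactate_per_biomass_b", "acetate_per_biomass_b")]) <= 0)) {
    stop("all yields must be > 0")
  }
  # carbon consumed by the degrader biomass reaction must exceed the carbon
  # it secretes as acids; otherwise the chain is carbon-imbalanced
  secreted <- 3 * p$lactate_per_biomass + 4 * p$succinate_per_biomass +
    2 * p$acetate_per_biomass
  p$biomass_carbon_d <- p$carbon_per_monomer * p$monomer_per_biomass - secreted
  if (p$biomass_carbon_d <= 0) {
    stop("carbon-imbalanced parameters: acids carry ", secreted,
         " C per biomass but only ",
         p$carbon_per_monomer * p$monomer_per_biomass, " C enter")
  }
  p
}

#' Synthetic degrader/butyrogen community with closed-form answer sheet
#'
#' @param params a [toy_community_params()].
#' @return list with elements `community` (a `community_model`), `scenario`
#'   (a [scenario_spec()]), `degrader`/`butyrogen` (the member networks),
#'   `medium`, `fiber` (a [fiber_spec()]) and `answers`, the analytic answer
#'   sheet: `mu_star` (maximum balanced growth), `u_min` (minimal fiber
#'   uptake at `mu_exp`), `u_prime` (suboptimal budget),
#'   `degrader_abundance_range` / `butyrogen_abundance_range` (FVA bounds at
#'   the suboptimal state), `u_min_of_mu` (function of mu), and
#'   `coupled_exchange` (the lactate exchange pair with coefficient -1).
#' @export
make_toy_degrader_butyrogen <- function(params = toy_community_params()) {
  stopifnot(inherits(params, "toy_community_params"))
  p <- params
  dp <- p$average_dp
  fiber_carbon <- dp * p$carbon_per_monomer

  mets_d <- data.frame(
    id = c("fiber_e", "monomer_c", "lactate_e", "succinate_e", "acetate_e"),
    name = c("fiber polymer", "monomer", "lactate", "succinate", "acetate"),
    formula = c(paste0("C", fiber_carbon), "C6H12O6", "C3H5O3", "C4H4O4",
                "C2H3O2"),
    compartment = c("e", "c", "e", "e", "e"),
    stringsAsFactors = FALSE)
  rxns_d <- data.frame(
    id = c("EX_fiber", "HYD", "BIO_D", "EX_lac", "EX_suc", "EX_ac"),
    name = c("fiber exchange", "fiber hydrolysis", "degrader biomass",
             "lactate exchange", "succinate exchange", "acetate exchange"),
    lower_bound = c(-p$fiber_uptake_cap, 0, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000, 1000),
    is_exchange = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  stoich_d <- list(
    EX_fiber = c(fiber_e = -1),
    HYD = c(fiber_e = -1, monomer_c = dp),
    BIO_D = c(monomer_c = -p$monomer_per_biomass,
              lactate_e = p$lactate_per_biomass,
              succinate_e = p$succinate_per_biomass,
              acetate_e = p$acetate_per_biomass),
    EX_lac = c(lactate_e = -1),
    EX_suc = c(succinate_e = -1),
    EX_ac = c(acetate_e = -1))
  degrader <- metabolic_network("toy_degrader", mets_d, rxns_d, stoich_d,
                                biomass_reaction_id = "BIO_D")

  mets_b <- data.frame(
    id = c("lactate_e", "acetate_e", "butyrate_e", "precursor_c"),
    name = c("lactate", "acetate", "butyrate", "biomass precursor"),
    formula = c("C3H5O3", "C2H3O2", "C4H7O2", NA),
    compartment = c("e", "e", "e", "c"),
    stringsAsFactors = FALSE)
  rxns_b <- data.frame(
    id = c("EX_lac", "EX_ac", "EX_but", "PREC_lac", "PREC_ac", "BUT", "BIO_B"),
    name = c("lactate exchange", "acetate exchange", "butyrate exchange",
             "biomass from lactate", "biomass from acetate",
             "butyrate fermentation", "butyrogen biomass"),
    lower_bound = c(-p$lactate_uptake_cap, -p$acetate_uptake_cap, 0, 0, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000, p$butyrate_cap, 1000),
    is_exchange = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  stoich_b <- list(
    EX_lac = c(lactate_e = -1),
    EX_ac = c(acetate_e = -1),
    EX_but = c(butyrate_e = -1),
    PREC_lac = c(lactate_e = -p$lactate_per_biomass_b, precursor_c = 1),
    PREC_ac = c(acetate_e = -p$acetate_per_biomass_b, precursor_c = 1),
    BUT = c(lactate_e = -2, butyrate_e = 1, acetate_e = 1),
    BIO_B = c(precursor_c = -1))
  butyrogen <- metabolic_network("toy_butyrogen", mets_b, rxns_b, stoich_b,
                                 biomass_reaction_id = "BIO_B")

  med <- medium(
    uptake_bounds = c(EX_fiber_e = 10),
    carbon_source_id = "EX_fiber_e",
    excess_value = 1000,
    export_bounds = c(EX_lactate_e = 0))  # lactate cannot leave the pool

  cm <- assemble_community(list(degrader = degrader, butyrogen = butyrogen),
                           med)
  scen <- scenario_spec(mu_exp = p$mu_exp, fiber_id = "fiber_e",
                        suboptimality_factor = p$suboptimality_factor)
  fiber <- fiber_spec("fiber_e", "monomer_c", dp, p$carbon_per_monomer)

  # closed forms from the linear yield chain:
  #   mu*      : fiber capacity limits the degrader, dp*capF/aM
  #   xD_min   : all secreted carbon feeds butyrogen growth exactly,
  #              1 / (1 + sL/aLb + sA/aAb)
  #   u_min(mu): aM * mu * xD_min / dp
  sL <- p$lactate_per_biomass; sA <- p$acetate_per_biomass
  aLb <- p$lactate_per_biomass_b; aAb <- p$acetate_per_biomass_b
  mu_star <- dp * p$fiber_uptake_cap / p$monomer_per_biomass
  xD_min <- 1 / (1 + sL / aLb + sA / aAb)
  u_min_of_mu <- function(mu) p$monomer_per_biomass * mu * xD_min / dp
  u_min <- u_min_of_mu(p$mu_exp)
  u_prime <- (1 + p$suboptimality_factor) * u_min
  xD_range <- c(xD_min, (1 + p$suboptimality_factor) * xD_min)

  answers <- list(
    mu_star = mu_star,
    u_min = u_min,
    u_min_of_mu = u_min_of_mu,
    u_prime = u_prime,
    degrader_abundance_range = xD_range,
    butyrogen_abundance_range = rev(1 - xD_range),
    degrader_lactate_range = sL * p$mu_exp * xD_range,
    coupled_exchange = c("degrader.EX_lac", "butyrogen.EX_lac")
  )
  list(community = cm, scenario = scen, degrader = degrader,
       butyrogen = butyrogen, medium = med, fiber = fiber,
       params = p, answers = answers)
}

#' Minimal balance-coupled two-member fixture
#'
#' Two members growing independently on a common substrate, plus one shared
#' metabolite produced by the first member (a capacity-bounded leak) and
#' consumed by the second, with no community sink. The pool balance row then
#' forces producer flux = -consumer flux in every feasible solution, so the
#' shared-exchange polytope is one-dimensional and the exchange pair is
#' perfectly anticorrelated. Abundances are pinned at one half each so every
#' stage runs in well under a second.
#'
#' @param seed RNG seed recorded with the fixture.
#' @param leak_cap leak capacity (mmol/gDW/h).
#' @param mu imposed community growth rate.
#' @return list with `community`, `scenario`, `answers` (fields
#'   `shared_range` — the producer-side FVA interval — and
#'   `coupled_exchange`).
#' @export
make_coupled_pair <- function(seed = 1, leak_cap = 5, mu = 0.5) {
  mets_p <- data.frame(
    id = c("subst_e", "shared_e"),
    name = c("substrate", "shared metabolite"),
    formula = c("C6H12O6", "C6H10O5"),
    compartment = "e", stringsAsFactors = FALSE)
  rxns_p <- data.frame(
    id = c("EX_sub", "BIO_P", "LEAK", "EX_shared"),
    name = c("substrate exchange", "biomass", "leak", "shared exchange"),
    lower_bound = c(-10, 0, 0, 0),
    upper_bound = c(1000, 1000, leak_cap, 1000),
    is_exchange = c(TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  stoich_p <- list(EX_sub = c(subst_e = -1),
                   BIO_P = c(subst_e = -2),
                   LEAK = c(subst_e = -1, shared_e = 1),
                   EX_shared = c(shared_e = -1))
  producer <- metabolic_network("toy_producer", mets_p, rxns_p, stoich_p,
                                biomass_reaction_id = "BIO_P")

  mets_c <- data.frame(
    id = c("subst_e", "shared_e", "waste_e"),
    name = c("substrate", "shared metabolite", "waste"),
    formula = c("C6H12O6", "C6H10O5", "C6H10O5"),
    compartment = "e", stringsAsFactors = FALSE)
  rxns_c <- data.frame(
    id = c("EX_sub", "BIO_C", "SINK", "EX_shared", "EX_waste"),
    name = c("substrate exchange", "biomass", "shared sink",
             "shared exchange", "waste exchange"),
    lower_bound = c(-10, 0, 0, -1000, 0),
    upper_bound = c(1000, 1000, 1000, 0, 1000),
    is_exchange = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  stoich_c <- list(EX_sub = c(subst_e = -1),
                   BIO_C = c(subst_e = -2),
                   SINK = c(shared_e = -1, waste_e = 1),
                   EX_shared = c(shared_e = -1),
                   EX_waste = c(waste_e = -1))
  consumer <- metabolic_network("toy_consumer", mets_c, rxns_c, stoich_c,
                                biomass_reaction_id = "BIO_C")

  med <- medium(uptake_bounds = c(EX_subst_e = 100),
                carbon_source_id = "EX_subst_e",
                export_bounds = c(EX_shared_e = 0))
  cm <- assemble_community(list(producer = producer, consumer = consumer),
                           med)
  scen <- scenario_spec(mu_exp = mu, fiber_id = "subst_e",
                        suboptimality_factor = 0,
                        fixed_abundances = c(producer = 0.5, consumer = 0.5))
  answers <- list(
    shared_range = c(0, leak_cap * 0.5),
    coupled_exchange = c("producer.EX_shared", "consumer.EX_shared"),
    seed = seed
  )
  list(community = cm, scenario = scen, producer = producer,
       consumer = consumer, medium = med, answers = answers)
}

#' Phenotype fixture with known confusion counts
#'
#' Builds a toy network whose substrate-growth and product-formation
#' behavior is known by construction, plus a truth table in which exactly
#' `round(error_rate * n_rows)` randomly chosen rows disagree with the model.
#'
#' @param n_rows number of truth-table rows (split between substrate and
#'   product assays).
#' @param error_rate fraction of rows flipped to disagree, in [0, 1].
#' @param seed RNG seed for choosing the flipped rows.
#' @return list with `network`, `medium`, `table` (a [phenotype_table()]),
#'   and `expected` (tp/tn/fp/fn plus the derived scores).
#' @export
make_phenotype_fixture <- function(n_rows = 12, error_rate = 0, seed = 1) {
  stopifnot(n_rows >= 2, error_rate >= 0, error_rate <= 1)
  ns <- ceiling(n_rows / 2)
  np <- n_rows - ns

  sub_ids <- paste0("sub", seq_len(ns))
  prod_ids <- if (np > 0) paste0("prod", seq_len(np)) else character(0)
  sub_grow <- seq_len(ns) %% 2L == 1L   # odd substrates support growth
  prod_make <- seq_len(np) %% 2L == 1L  # odd products can be formed

  mets <- data.frame(
    id = c(paste0(sub_ids, "_e"), paste0(prod_ids, "_e"), "core_c"),
    name = c(sub_ids, prod_ids, "core precursor"),
    formula = c(rep("C6H12O6", ns), rep("C3H6O3", np), NA),
    compartment = c(rep("e", ns + np), "c"),
    stringsAsFactors = FALSE)

  rxns <- list(); stoich <- list()
  add <- function(id, name, lb, ub, ex, s) {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, name = name, lower_bound = lb, upper_bound = ub,
      is_exchange = ex, stringsAsFactors = FALSE)
    stoich[[id]] <<- s
  }
  for (i in seq_len(ns)) {
    add(paste0("EX_", sub_ids[i]), paste(sub_ids[i], "exchange"),
        -10, 1000, TRUE, stats::setNames(-1, paste0(sub_ids[i], "_e")))
    if (sub_grow[i]) {
      add(paste0("CAT_", sub_ids[i]), paste("catabolism of", sub_ids[i]),
          0, 1000, FALSE,
          stats::setNames(c(-1, 1), c(paste0(sub_ids[i], "_e"), "core_c")))
    }
  }
  for (j in seq_len(np)) {
    add(paste0("EX_", prod_ids[j]), paste(prod_ids[j], "exchange"),
        0, 1000, TRUE, stats::setNames(-1, paste0(prod_ids[j], "_e")))
    if (prod_make[j]) {
      add(paste0("SYN_", prod_ids[j]), paste("synthesis of", prod_ids[j]),
          0, 1000, FALSE,
          stats::setNames(c(-1, 2), c("core_c", paste0(prod_ids[j], "_e"))))
    }
  }
  add("BIO", "biomass", 0, 1000, FALSE, c(core_c = -1))
  net <- metabolic_network("toy_phenotype", mets, do.call(rbind, rxns),
                           stoich, biomass_reaction_id = "BIO")

  med <- medium(uptake_bounds = stats::setNames(10, paste0("EX_", sub_ids[1])),
                carbon_source_id = paste0("EX_", sub_ids[1]))

  model_positive <- c(sub_grow, prod_make)
  rows <- data.frame(
    compound_id = c(paste0("EX_", sub_ids), paste0("EX_", prod_ids)),
    assay_kind = c(rep("substrate_growth", ns),
                   rep("product_formation", np)),
    experimental = ifelse(model_positive, "positive", "negative"),
    note = "synthetic truth",
    stringsAsFactors = FALSE)

  n_flip <- round(error_rate * n_rows)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  flip <- sample.int(n_rows, n_flip)
  flipped <- logical(n_rows); flipped[flip] <- TRUE
  rows$experimental[flipped] <- ifelse(model_positive[flipped],
                                       "negative", "positive")
  rows$note[flipped] <- "synthetic truth (flipped)"

  tp <- sum(model_positive & !flipped)
  fp <- sum(model_positive & flipped)
  tn <- sum(!model_positive & !flipped)
  fn <- sum(!model_positive & flipped)
  expected <- list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    accuracy = (tp + tn) / n_rows,
    f_score = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
              else NA_real_)
  list(network = net, medium = med, table = phenotype_table(rows),
       expected = expected, model_positive = model_positive,
       flipped = flipped)
}
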