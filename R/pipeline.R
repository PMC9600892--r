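# End-to-end scenario runner: load -> curate -> medium/fiber -> validate ->
# SteadyCom -> suboptimal FVA -> sample -> classify, driven by one YAML
# config, with per-stage outputs written as soon as each stage completes and
# a manifest (config snapshot, timings, checksums, seed) at the end.

#' Run a community cross-feeding scenario from a config file
#'
#' The YAML config has the following keys (paths are resolved relative to
#' the config file):
#' * `models`: map member tag -> `{path, format}`;
#' * `curation` (optional): map member tag -> curation YAML;
#' * `medium`: community medium YAML;
#' * `fiber` (optional): `{member, fiber_id, monomer_id, average_dp,
#'   carbon_per_monomer}` for carbon normalization of the fiber polymer;
#' * `scenario`: `{mu_exp, fiber_id, suboptimality_factor, total_abundance}`;
#' * `sampler` (optional): `{n_samples, thinning, n_warmup}`;
#' * `validation` (optional): map member tag -> phenotype CSV;
#' * `alpha` (optional): significance level for exchange classification.
#'
#' @param config_path YAML config file.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling the sampler.
#' @param force overwrite an existing non-empty output directory.
#' @return a `scenario_run_record`: config snapshot, stage timings, file
#'   manifest, package version and seed (also written as `manifest.json`).
#' @export
run_scenario <- function(config_path, out_dir, seed = 1, force = FALSE) {
  config <- yaml::read_yaml(config_path)
  base_dir <- dirname(normalizePath(config_path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE to overwrite")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  timings <- list()
  files <- character(0)
  stage_name <- "init"

  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage_name,
                   "] ", ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    stage_name <<- name
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      err <- list(stage = name, error = conditionMessage(e),
                  completed_stages = names(timings))
      jsonlite::write_json(err, file.path(out_dir, "error_manifest.json"),
                           auto_unbox = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    log_msg(sprintf("done in %.2f s", timings[[name]]))
    out
  }
  emit <- function(obj, fname, writer) {
    path <- file.path(out_dir, fname)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  write_csv <- function(obj, path) {
    utils::write.csv(obj, path, row.names = FALSE)
  }
  write_json <- function(obj, path) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  members <- stage("load_models", {
    ms <- lapply(config$models, function(m) {
      read_model(resolve(m$path), format = m$format %||% "json")
    })
    log_msg("loaded ", length(ms), " member model(s): ",
            paste(names(ms), collapse = ", "))
    ms
  })

  if (!is.null(config$curation)) {
    members <- stage("curation", {
      for (tag in names(config$curation)) {
        edits <- read_curation_yaml(resolve(config$curation[[tag]]))
        members[[tag]] <- apply_curation(members[[tag]], edits)
        log_msg("applied ", length(edits), " edit(s) to ", tag)
      }
      members
    })
  }

  med <- stage("medium", read_medium_yaml(resolve(config$medium)))

  if (!is.null(config$fiber)) {
    members <- stage("fiber_normalization", {
      f <- config$fiber
      fs <- fiber_spec(f$fiber_id, f$monomer_id, f$average_dp,
                       f$carbon_per_monomer)
      members[[f$member]] <- normalize_fiber_polymer(members[[f$member]], fs)
      members
    })
  }

  if (!is.null(config$validation)) {
    stage("validation", {
      for (tag in names(config$validation)) {
        tbl <- read_phenotype_csv(resolve(config$validation[[tag]]))
        pred <- predict_phenotypes(members[[tag]], tbl, med)
        res <- score_validation(pred, tbl)
        emit(res$per_row_verdicts, paste0("validation_", tag, ".csv"),
             write_csv)
        emit(res[c("tp", "tn", "fp", "fn", "precision", "recall",
                   "accuracy", "f_score")],
             paste0("validation_", tag, ".json"), write_json)
        log_msg(tag, ": F-score ", format(res$f_score, digits = 4))
      }
    })
  }

  cm <- stage("assemble", assemble_community(members, med))
  sc <- config$scenario
  scenario <- scenario_spec(mu_exp = sc$mu_exp, fiber_id = sc$fiber_id,
                            suboptimality_factor =
                              sc$suboptimality_factor %||% 0.05,
                            total_abundance = sc$total_abundance %||% 1)

  optimal <- stage("steadycom", {
    sol <- min_fiber_uptake(cm, scenario$mu_exp, scenario$fiber_id,
                            scenario$total_abundance)
    check <- check_steadycom_solution(cm, sol)
    if (!isTRUE(check)) stop("solution check failed: ",
                             paste(check, collapse = "; "))
    emit(list(mu = sol$mu, abundances = as.list(sol$abundances),
              fiber_uptake = sol$fiber_uptake,
              pool_exchanges = as.list(sol$pool_exchanges)),
         "solution_optimal.json", write_json)
    emit(sol$exchange_fluxes, "exchange_fluxes_optimal.csv", write_csv)
    log_msg("minimal fiber uptake ", format(sol$fiber_uptake, digits = 6),
            " mmol/h at mu = ", scenario$mu_exp)
    sol
  })

  budget <- stage("suboptimal_budget", suboptimal_budget(cm, scenario))
  log_msg("fiber budget u' = ", format(budget, digits = 6))

  fva <- stage("fva", {
    r <- community_fva(cm, scenario, fiber_budget = budget)
    emit(r, "fva.csv", write_csv)
    r
  })

  stage("fig2_table", {
    opt_val <- vapply(fva$quantity, function(q) {
      unname(optimal$raw[q])
    }, numeric(1))
    tab <- data.frame(quantity = fva$quantity, optimal = opt_val,
                      fva_min = fva$min, fva_max = fva$max,
                      stringsAsFactors = FALSE)
    emit(tab, "exchange_table.csv", write_csv)
  })

  samples <- stage("sampling", {
    smp <- config$sampler
    cfg <- sampler_config(n_samples = smp$n_samples %||% 20000,
                          thinning = smp$thinning %||% 100,
                          n_warmup = smp$n_warmup,
                          seed = seed)
    s <- sample_hit_and_run(cm, scenario, cfg, fiber_budget = budget)
    emit(as.data.frame(unclass(s)), "samples.csv", write_csv)
    s
  })

  stage("classification", {
    rep <- classify_exchanges(samples, alpha = config$alpha %||% 0.01)
    emit(rep$classification, "classification.csv", write_csv)
    emit(as.data.frame(rep$correlation), "correlation.csv",
         function(obj, path) utils::write.csv(obj, path, row.names = TRUE))
    dens <- summarize_densities(samples)
    emit(dens, "densities.json", write_json)
    rep
  })

  record <- structure(list(
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("steadycross")),
    stage_timings = timings,
    file_manifest = data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE)
  ), class = "scenario_run_record")
  stage_name <- "manifest"
  jsonlite::write_json(
    list(config = config, seed = seed,
         package_version = record$package_version,
         stage_timings = timings,
         file_manifest = record$file_manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  log_msg("run complete; ", length(files), " output file(s)")
  record
}

#' @export
print.scenario_run_record <- function(x, ...) {
  cat("<scenario_run_record> seed ", x$seed, ", version ",
      x$package_version, "\n", sep = "")
  for (s in names(x$stage_timings)) {
    cat(sprintf("  %-20s %8.2f s\n", s, x$stage_timings[[s]]))
  }
  invisible(x)
}
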