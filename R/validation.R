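# Phenotype validation: does the model grow on the substrates the organism is
# known to use, and can it form the fermentation products it is known to make?
# Predictions are scored against an experimental truth table with the usual
# binary-classification statistics (precision, recall, accuracy, F-score).

#' Construct a phenotype truth table
#'
#' @param rows data.frame with columns `compound_id` (exchange reaction id),
#'   `assay_kind` (`"substrate_growth"` or `"product_formation"`),
#'   `experimental` (`"positive"` or `"negative"`), and optional `note`.
#' @return a `phenotype_table` object.
#' @export
phenotype_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (!"note" %in% names(rows)) rows$note <- ""
  stopifnot(all(c("compound_id", "assay_kind", "experimental") %in% names(rows)))
  if (!all(rows$assay_kind %in% c("substrate_growth", "product_formation"))) {
    stop("assay_kind must be substrate_growth or product_formation")
  }
  if (!all(rows$experimental %in% c("positive", "negative"))) {
    stop("experimental must be positive or negative")
  }
  if (anyDuplicated(rows[c("compound_id", "assay_kind")])) {
    stop("compound_id must be unique within each assay_kind")
  }
  structure(list(rows = rows), class = "phenotype_table")
}

#' Read a phenotype table from CSV
#'
#' Columns: `compound_id`, `assay_kind`, `experimental`, optional `note`.
#'
#' @param path CSV file path.
#' @return a [phenotype_table()].
#' @export
read_phenotype_csv <- function(path) {
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Predict substrate-utilization and product-formation phenotypes
#'
#' For `substrate_growth` rows the compound's exchange replaces the medium's
#' carbon source (all other carbon uptakes closed) and the prediction is
#' positive iff optimal growth exceeds `growth_epsilon`. For
#' `product_formation` rows the model grows on the given medium and the
#' prediction is positive iff the maximal secretion flux of the compound
#' exceeds `flux_epsilon` while growth is held at
#' `fraction_of_optimum * mu_star`. Compounds without an exchange reaction
#' are predicted negative and flagged.
#'
#' @param net a `metabolic_network`.
#' @param table a [phenotype_table()].
#' @param med the base [medium()]; must support growth.
#' @param growth_epsilon minimum growth rate (h^-1) counted as growth.
#' @param flux_epsilon minimum secretion flux (mmol/gDW/h) counted as
#'   production.
#' @param fraction_of_optimum fraction of optimal growth enforced during
#'   product tests.
#' @return data.frame with columns `compound_id`, `assay_kind`, `predicted`
#'   (`"positive"`/`"negative"`) and `flagged` (no exchange reaction).
#' @export
predict_phenotypes <- function(net, table, med,
                               growth_epsilon = 1e-6,
                               flux_epsilon = 1e-6,
                               fraction_of_optimum = 0.9) {
  stopifnot(inherits(table, "phenotype_table"))
  base <- apply_medium(net, med)
  base_opt <- fba(base)
  if (base_opt$status != "optimal") {
    stop("base medium is infeasible for model '", net$model_id,
         "'; no phenotype can be scored")
  }
  rows <- table$rows
  predicted <- character(nrow(rows))
  flagged <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    cid <- rows$compound_id[i]
    if (!cid %in% net$reactions$id ||
        !net$reactions$is_exchange[rxn_index(net, cid)]) {
      predicted[i] <- "negative"
      flagged[i] <- TRUE
      next
    }
    if (rows$assay_kind[i] == "substrate_growth") {
      m2 <- med
      m2$uptake_bounds <- m2$uptake_bounds[
        names(m2$uptake_bounds) != m2$carbon_source_id]
      m2$uptake_bounds[cid] <- max(med$uptake_bounds[[med$carbon_source_id]],
                                   10)
      m2$carbon_source_id <- cid
      g <- fba(apply_medium(net, m2))
      predicted[i] <- if (g$status == "optimal" &&
                          g$objective_value > growth_epsilon) {
        "positive"
      } else "negative"
    } else {
      test <- base
      bi <- rxn_index(test, test$biomass_reaction_id)
      test$reactions$lower_bound[bi] <-
        fraction_of_optimum * base_opt$objective_value
      sec <- fba(test, objective = cid, maximize = TRUE)
      predicted[i] <- if (sec$status == "optimal" &&
                          sec$objective_value > flux_epsilon) {
        "positive"
      } else "negative"
    }
  }
  data.frame(compound_id = rows$compound_id, assay_kind = rows$assay_kind,
             predicted = predicted, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Score phenotype predictions against the truth table
#'
#' Counts true/false positives/negatives treating the experimental call as
#' truth, and derives precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/n and F-score = 2TP/(2TP+FP+FN) in exact arithmetic on
#' the counts.
#'
#' @param predicted data.frame from [predict_phenotypes()] (or any data.frame
#'   with a `predicted` column aligned row-by-row with the table).
#' @param table a [phenotype_table()].
#' @return a `validation_result`: list with `tp`, `tn`, `fp`, `fn`,
#'   `precision`, `recall`, `accuracy`, `f_score` and `per_row_verdicts`.
#' @export
score_validation <- function(predicted, table) {
  stopifnot(inherits(table, "phenotype_table"))
  rows <- table$rows
  if (nrow(predicted) != nrow(rows)) {
    stop("predicted has ", nrow(predicted), " rows but the table has ",
         nrow(rows))
  }
  exp_pos <- rows$experimental == "positive"
  pred_pos <- predicted$predicted == "positive"
  tp <- sum(pred_pos & exp_pos)
  tn <- sum(!pred_pos & !exp_pos)
  fp <- sum(pred_pos & !exp_pos)
  fn <- sum(!pred_pos & exp_pos)
  verdict <- ifelse(pred_pos & exp_pos, "TP",
             ifelse(!pred_pos & !exp_pos, "TN",
             ifelse(pred_pos, "FP", "FN")))
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    accuracy = (tp + tn) / nrow(rows),
    f_score = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    per_row_verdicts = data.frame(compound_id = rows$compound_id,
                                  assay_kind = rows$assay_kind,
                                  experimental = rows$experimental,
                                  predicted = predicted$predicted,
                                  verdict = verdict,
                                  stringsAsFactors = FALSE)
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>\n")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  precision %.3f  recall %.3f  accuracy %.3f  F-score %.3f\n",
              x$precision, x$recall, x$accuracy, x$f_score))
  invisible(x)
}
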