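# Cross-feeding statistics on sampled exchange fluxes.
#
# A member's exchanged metabolite is called produced when the sampled flux
# distribution's median is significantly greater than zero, consumed when it
# is significantly less than zero (one-sample Wilcoxon signed-rank test
# against zero), and indeterminate otherwise. Coupling between members'
# exchanges is quantified by pairwise correlation across samples.

#' Classify exchanged metabolites as produced, consumed or indeterminate
#'
#' Each column of the sample matrix is tested against a zero median with the
#' one-sample Wilcoxon signed-rank test. Classification follows the sign of
#' the median at significance level `alpha`: `produced` iff median > 0 and
#' p < alpha, `consumed` iff median < 0 and p < alpha, otherwise
#' `indeterminate`. Constant all-zero columns are indeterminate with p = 1
#' and flagged. No multiple-testing correction is applied; p-values are
#' reported raw. Note that thinned Markov-chain samples remain
#' autocorrelated, which inflates the nominal significance; interpret p
#' relative to the configured threshold, not as an exact error rate.
#'
#' @param samples a `flux_sample_matrix` (or any numeric matrix with named
#'   columns).
#' @param alpha significance level (default 0.01).
#' @return an `exchange_report`: list with `classification` (data.frame:
#'   `quantity`, `median`, `p_value`, `classification`, `flagged`),
#'   `correlation` (matrix from [exchange_correlation()]), and `alpha`.
#' @export
classify_exchanges <- function(samples, alpha = 0.01) {
  if (nrow(samples) < 2) stop("need at least 2 samples per column")
  cols <- colnames(samples)
  med <- numeric(length(cols)); pv <- numeric(length(cols))
  cls <- character(length(cols)); flag <- logical(length(cols))
  for (i in seq_along(cols)) {
    x <- samples[, i]
    med[i] <- stats::median(x)
    if (all(x == 0)) {
      pv[i] <- 1; cls[i] <- "indeterminate"; flag[i] <- TRUE
      next
    }
    pv[i] <- suppressWarnings(
      stats::wilcox.test(x, mu = 0, exact = FALSE)$p.value)
    cls[i] <- if (pv[i] < alpha && med[i] > 0) {
      "produced"
    } else if (pv[i] < alpha && med[i] < 0) {
      "consumed"
    } else "indeterminate"
  }
  structure(list(
    classification = data.frame(quantity = cols, median = med, p_value = pv,
                                classification = cls, flagged = flag,
                                stringsAsFactors = FALSE),
    correlation = exchange_correlation(samples),
    alpha = alpha
  ), class = "exchange_report")
}

#' @export
print.exchange_report <- function(x, ...) {
  cat("<exchange_report> alpha =", x$alpha, "\n")
  print(x$classification, row.names = FALSE)
  invisible(x)
}

#' Pairwise coupling between exchange fluxes
#'
#' Correlation matrix over all non-constant sample columns; constant columns
#' are excluded and recorded in the `"excluded"` attribute. Exchange pairs
#' that are exactly balance-coupled (a shared metabolite with no community
#' sink, so producer flux = -consumer flux in every solution) yield a
#' coefficient of -1.
#'
#' @param samples numeric sample matrix with named columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
exchange_correlation <- function(samples, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(samples) < 3) stop("need at least 3 samples for correlations")
  sds <- apply(samples, 2L, stats::sd)
  keep <- sds > 0
  excluded <- colnames(samples)[!keep]
  cm <- stats::cor(samples[, keep, drop = FALSE], method = method)
  attr(cm, "excluded") <- excluded
  cm
}

#' Per-column density summaries of sampled exchange fluxes
#'
#' For each column: a fixed-rule histogram (Freedman-Diaconis bin width,
#' falling back to Sturges for zero-IQR columns), the median, and the
#' 2.5/97.5 percentiles — the numbers behind the usual flux density plots.
#' Medians are computed by the same call as in [classify_exchanges()], so
#' the two reports agree exactly.
#'
#' @param samples numeric sample matrix with named columns.
#' @return named list, one entry per column, each a list with `median`,
#'   `q025`, `q975`, `breaks` and `counts`.
#' @export
summarize_densities <- function(samples) {
  out <- lapply(seq_len(ncol(samples)), function(i) {
    x <- samples[, i]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    if (stats::IQR(x) > 0) {
      hh <- graphics::hist(x, breaks = "FD", plot = FALSE)
    } else if (diff(range(x)) > 0) {
      hh <- graphics::hist(x, breaks = "Sturges", plot = FALSE)
    } else {
      # constant column: a single occupied bin around the value
      hh <- list(breaks = x[1] + c(-0.5, 0.5), counts = length(x))
    }
    list(median = stats::median(x), q025 = q[1], q975 = q[2],
         breaks = hh$breaks, counts = hh$counts)
  })
  names(out) <- colnames(samples)
  out
}
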