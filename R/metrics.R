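#' Kolmogorov-Smirnov normality check for TWAS Z-scores
#'
#' One-sample KS test of the Z-scores against the standard normal; under a
#' well-calibrated null the test statistic should be small and the p-value
#' approximately uniform.
#'
#' @param zs numeric vector of TWAS Z-scores (at least 10 finite values).
#' @return A list with `stat` and `pvalue`.
#' @export
ks_normality <- function(zs) {
  zs <- zs[is.finite(zs)]
  if (length(zs) < 10) abort("at least 10 finite Z-scores are required.")
  if (sd(zs) == 0) abort("Z-scores are constant; KS test is undefined.")
  res <- suppressWarnings(ks.test(zs, "pnorm"))
  list(stat = unname(res$statistic), pvalue = res$p.value)
}

#' Rejection rates: family-wise error rate and power
#'
#' Both are the fraction of replicates whose p-value falls below the
#' significance threshold; `fwer()` is the per-gene rejection rate under a
#' null generative model at the transcriptome-wide threshold, `power_rate()`
#' the same quantity under a causal (or linkage) model. The default
#' threshold `2.27e-6` corresponds to a Bonferroni correction for roughly
#' 22,000 genes at the 0.05 level.
#'
#' @param pvals numeric vector of p-values; non-finite entries (missing
#'   TWAS results) are excluded.
#' @param threshold significance threshold in (0, 1).
#' @return The rejection proportion.
#' @export
fwer <- function(pvals, threshold = 2.27e-6) {
  check_scalar(threshold, "threshold", 0, 1, lower_open = TRUE,
               upper_open = TRUE)
  pvals <- pvals[is.finite(pvals)]
  if (length(pvals) == 0) abort("no finite p-values supplied.")
  mean(pvals < threshold)
}

#' @rdname fwer
#' @export
power_rate <- function(pvals, threshold = 2.27e-6) {
  fwer(pvals, threshold)
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(z^2) / qchisq(0.5, 1)`; values near 1 indicate a
#' calibrated null, values above 1 inflation.
#'
#' @param zs numeric vector of Z-scores (at least 10 finite values).
#' @return The inflation factor.
#' @export
genomic_inflation <- function(zs) {
  zs <- zs[is.finite(zs)]
  if (length(zs) < 10) abort("at least 10 finite Z-scores are required.")
  median(zs^2) / qchisq(0.5, df = 1)
}

#' Summarize TWAS replicates into calibration and power metrics
#'
#' Groups a results table by prediction model and computes the KS
#' normality test, genomic inflation, the rejection rate at the
#' transcriptome-wide threshold (interpretable as FWER under a null run
#' and as power under a causal run), and the rejection rate at nominal
#' 0.05. Missing (degenerate) TWAS results are excluded and counted.
#'
#' @param results a tibble with columns `model`, `z_twas`, `pvalue`
#'   (e.g. from [run_experiment()]).
#' @param threshold transcriptome-wide significance threshold.
#' @return A tibble of class `metrics_report`, one row per model, with
#'   columns `model`, `n_replicates`, `n_missing`, `ks_stat`, `ks_pvalue`,
#'   `lambda_gc`, `fwer`, `power`, `reject_nominal`, `threshold`.
#' @export
twas_metrics <- function(results, threshold = 2.27e-6) {
  stopifnot(all(c("model", "z_twas", "pvalue") %in% names(results)))
  # small batches (< 10 finite Z) report NA for the distributional metrics
  safe_ks <- function(zs) {
    tryCatch(ks_normality(zs), error = function(e) {
      list(stat = NA_real_, pvalue = NA_real_)
    })
  }
  safe_gc <- function(zs) {
    tryCatch(genomic_inflation(zs), error = function(e) NA_real_)
  }
  out <- results |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_missing = sum(!is.finite(.data$z_twas)),
      ks_stat = safe_ks(.data$z_twas)$stat,
      ks_pvalue = safe_ks(.data$z_twas)$pvalue,
      lambda_gc = safe_gc(.data$z_twas),
      fwer = fwer(.data$pvalue, threshold),
      power = power_rate(.data$pvalue, threshold),
      reject_nominal = fwer(.data$pvalue, 0.05),
      threshold = threshold,
      .groups = "drop"
    )
  class(out) <- c("metrics_report", class(out))
  out
}
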