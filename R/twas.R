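#' Gene-level TWAS association statistic
#'
#' Combines prediction weights with GWAS Z-scores under a testing-stage LD
#' reference: `z_twas = (w' z) / sqrt(w' R w)` with `R` the regularized
#' testing LD. SNPs must match in identity and order across the three
#' inputs; any mismatch is a hard error rather than a silent intersection.
#' An undefined statistic (quadratic form at or below 1e-12, e.g. all-zero
#' weights) is reported as missing, never as zero.
#'
#' @param w a [weight_vector()].
#' @param gwas a `gwas_summary` ([marginal_scan()] or
#'   [simulate_summary_fast()]).
#' @param ld_test an `ld_reference` for the testing stage.
#' @param replicate_id optional replicate index recorded in the result.
#' @param config_digest optional configuration fingerprint.
#' @return A one-row tibble of class `twas_result` with columns `z_twas`,
#'   `pvalue`, `model`, `fit_r2`, `degenerate`, `replicate`,
#'   `config_digest`, `ld_gwas`, `ld_test`, `n_gwas`, `gwas_mode`.
#' @export
twas_statistic <- function(w, gwas, ld_test, replicate_id = NA_integer_,
                           config_digest = NA_character_) {
  stopifnot(inherits(w, "weight_vector"),
            inherits(gwas, "gwas_summary"),
            inherits(ld_test, "ld_reference"))
  p <- length(w$w)
  if (nrow(gwas) != p || nrow(ld_test$corr) != p) {
    abort("weights, GWAS summary, and testing LD must have equal length.")
  }
  ids <- names(w$w)
  if (!is.null(ids) &&
      (!identical(ids, gwas$id) || !identical(ids, ld_test$snps$id))) {
    abort("SNP identifiers do not match in order across weights, GWAS, and testing LD.")
  }
  q <- as.numeric(t(w$w) %*% ld_test$reg %*% w$w)
  if (q < -1e-10) {
    abort("negative quadratic form: testing LD is not positive semi-definite.")
  }
  degenerate <- q <= 1e-12
  z <- if (degenerate) NA_real_ else sum(w$w * gwas$z) / sqrt(q)
  out <- tibble(
    z_twas = z,
    pvalue = if (degenerate) NA_real_ else 2 * pnorm(-abs(z)),
    model = w$model_label,
    fit_r2 = w$fit_r2,
    degenerate = degenerate,
    replicate = as.integer(replicate_id),
    config_digest = config_digest,
    ld_gwas = attr(gwas, "ld_source") %||% NA_character_,
    ld_test = ld_test$source_label,
    n_gwas = attr(gwas, "n_gwas") %||% NA_integer_,
    gwas_mode = attr(gwas, "mode_label") %||% NA_character_
  )
  class(out) <- c("twas_result", class(out))
  out
}
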