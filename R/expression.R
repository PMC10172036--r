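#' Simulate an eQTL reference cohort with expression
#'
#' Samples `n_qtl` individuals from the eQTL-stage LD reference, builds
#' expression as `expr = X b + e` with residual variance `1 - h2g`, and
#' standardizes the expression vector to mean 0, variance 1 before model
#' fitting. The realized cis-heritability (sample variance fraction of the
#' genetic component) is recorded.
#'
#' @param ld an `ld_reference` for the eQTL stage.
#' @param eqtl an [sample_eqtl_architecture()].
#' @param n_qtl eQTL cohort size (>= 2).
#' @param seed integer seed.
#' @return An object of class `expression_panel` with fields `panel`
#'   (a [genotype_panel()]), `expr`, and `h2g_realized`.
#' @export
simulate_expression_panel <- function(ld, eqtl, n_qtl, seed) {
  stopifnot(inherits(ld, "ld_reference"),
            inherits(eqtl, "eqtl_architecture"))
  n_qtl <- check_count(n_qtl, "n_qtl", lower = 2)
  if (eqtl$h2g > 1) abort("`h2g` cannot exceed 1.")
  seed <- check_seed(seed)
  panel <- sample_genotypes(ld, n_qtl, seed)
  with_seed(seed + 1L, {
    g <- as.numeric(panel$dosages %*% eqtl$b)
    e <- rnorm(n_qtl, sd = sqrt(1 - eqtl$h2g))
    raw <- g + e
    var_raw <- mean((raw - mean(raw))^2)
    h2g_realized <- if (var_raw > 0) mean((g - mean(g))^2) / var_raw else 0
    expr <- standardize_vector(raw)
    structure(
      list(panel = panel, expr = expr, h2g_realized = h2g_realized),
      class = "expression_panel"
    )
  })
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf(
    "<expression_panel> n_qtl = %d, P = %d, realized h2g = %.3f\n",
    nrow(x$panel$dosages), ncol(x$panel$dosages), x$h2g_realized
  ))
  invisible(x)
}
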