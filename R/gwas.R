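new_gwas_summary <- function(snps, z, n_gwas, mode_label, ld_source) {
  z <- unname(z)
  p <- 2 * pnorm(-abs(z))
  out <- tibble(
    id = snps$id, a0 = snps$a0, a1 = snps$a1,
    z = z, p = p
  )
  attr(out, "n_gwas") <- n_gwas
  attr(out, "mode_label") <- mode_label
  attr(out, "ld_source") <- ld_source
  class(out) <- c("gwas_summary", class(out))
  out
}

#' Simulate a quantitative trait from individual genotypes
#'
#' Builds a phenotype with population variance 1 under the configured
#' trait model: causal mode uses `y = alpha * (X b) / sqrt(h2g) + e` with
#' residual variance `1 - h2ge`; null mode is pure noise with variance 1;
#' linkage mode uses `y = X linkage_b + e` with residual variance
#' `1 - h2ge`.
#'
#' @param panel a [genotype_panel()] (e.g. from [sample_genotypes()]).
#' @param eqtl an [sample_eqtl_architecture()] of matching dimension.
#' @param trait a `trait_model` ([causal_trait()], [null_trait()], or
#'   [sample_linkage_architecture()]).
#' @param seed integer seed for the residual noise.
#' @return A numeric phenotype vector of length `nrow(panel$dosages)`.
#' @export
simulate_trait <- function(panel, eqtl, trait, seed) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(eqtl, "eqtl_architecture"),
            inherits(trait, "trait_model"))
  if (ncol(panel$dosages) != length(eqtl$b)) {
    abort("panel SNP count must match the architecture length.")
  }
  n <- nrow(panel$dosages)
  with_seed(seed, {
    switch(trait$mode,
      null = rnorm(n),
      causal = {
        if (eqtl$h2g == 0 && trait$h2ge > 0) {
          abort(paste0(
            "causal trait with h2ge > 0 requires h2g > 0 ",
            "(standardized expression score is undefined at h2g = 0)."
          ))
        }
        g <- if (trait$h2ge > 0) {
          as.numeric(panel$dosages %*% eqtl$b) / sqrt(eqtl$h2g)
        } else {
          0
        }
        trait$alpha * g + rnorm(n, sd = sqrt(1 - trait$h2ge))
      },
      linkage = {
        as.numeric(panel$dosages %*% trait$linkage_b) +
          rnorm(n, sd = sqrt(1 - trait$h2ge))
      },
      abort(sprintf("unknown trait mode '%s'", trait$mode))
    )
  })
}

#' Marginal association scan (standard mode)
#'
#' Per-SNP simple linear regression of the phenotype on each standardized
#' dosage column (intercept absorbed by centering), returning Wald
#' Z-scores `slope / se` with `se = sqrt(RSS / (n - 2)) / sqrt(sum x^2)`.
#' Degenerate fits (zero residual variance) are capped at `|z| = 1e8`
#' with a warning so downstream p-value math stays total.
#'
#' @param panel a [genotype_panel()].
#' @param y numeric phenotype vector, one value per sample.
#' @return A `gwas_summary` tibble (columns `id`, `a0`, `a1`, `z`, `p`)
#'   with attributes `n_gwas`, `mode_label = "standard"`, `ld_source`.
#' @export
marginal_scan <- function(panel, y) {
  stopifnot(inherits(panel, "genotype_panel"))
  x <- panel$dosages
  n <- nrow(x)
  if (length(y) != n) abort("phenotype length must match the panel.")
  if (n < 3) abort("at least 3 samples are required for a marginal scan.")
  y <- y - mean(y)
  xty <- as.numeric(crossprod(x, y))
  xtx <- colSums(x * x)
  slope <- xty / xtx
  rss <- pmax(sum(y * y) - slope * xty, 0)
  se <- sqrt(rss / (n - 2)) / sqrt(xtx)
  z <- slope / se
  bad <- !is.finite(z) | abs(z) > 1e8
  if (any(bad)) {
    warn(sprintf("capped %d degenerate Z-score(s) at +/-1e8", sum(bad)))
    z[bad] <- sign(slope[bad]) * 1e8
    z[bad & slope[bad] == 0] <- 0
  }
  new_gwas_summary(panel$snps, z, n_gwas = n, mode_label = "standard",
                   ld_source = panel$source)
}

#' Simulate GWAS summary statistics directly (fast mode)
#'
#' Draws per-SNP Z-scores from the LD-parameterized multivariate normal
#' `z ~ MVN(sqrt(N) * R * beta, R)` where `R` is the regularized LD and
#' `beta` is the standardized joint SNP-effect vector implied by the trait
#' model (causal: `alpha * b / sqrt(h2g)`; null: 0; linkage: `linkage_b`).
#' Memory use depends only on `P`, never on `n_gwas`.
#'
#' @param ld an `ld_reference` (GWAS-stage panel).
#' @param eqtl an [sample_eqtl_architecture()].
#' @param trait a `trait_model`.
#' @param n_gwas GWAS sample size (enters only through the mean).
#' @param seed integer seed.
#' @return A `gwas_summary` tibble with `mode_label = "fast"`.
#' @export
simulate_summary_fast <- function(ld, eqtl, trait, n_gwas, seed) {
  stopifnot(inherits(ld, "ld_reference"),
            inherits(eqtl, "eqtl_architecture"),
            inherits(trait, "trait_model"))
  n_gwas <- check_count(n_gwas, "n_gwas", lower = 1)
  p <- nrow(ld$corr)
  if (length(eqtl$b) != p) {
    abort("architecture length must match the LD reference.")
  }
  beta <- switch(trait$mode,
    null = numeric(p),
    causal = {
      if (eqtl$h2g == 0 && trait$h2ge > 0) {
        abort("causal trait with h2ge > 0 requires h2g > 0.")
      }
      if (trait$h2ge > 0) trait$alpha * eqtl$b / sqrt(eqtl$h2g)
      else numeric(p)
    },
    linkage = trait$linkage_b,
    abort(sprintf("unknown trait mode '%s'", trait$mode))
  )
  with_seed(seed, {
    mu <- sqrt(n_gwas) * as.numeric(ld$reg %*% beta)
    z <- mu + as.numeric(ld$factor %*% rnorm(p))
    new_gwas_summary(ld$snps, z, n_gwas = n_gwas, mode_label = "fast",
                     ld_source = ld$source_label)
  })
}
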