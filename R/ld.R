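#' LD reference objects
#'
#' An `ld_reference` stores the `P x P` SNP correlation matrix of a panel,
#' its ridge-regularized version `(R + eps * I) / (1 + eps)` (which keeps a
#' unit diagonal), and the lower-triangular Cholesky factor of the
#' regularized matrix used for multivariate-normal sampling.
#'
#' @name ld_reference
NULL

new_ld_reference <- function(corr, ridge_eps, snps, source_label) {
  p <- nrow(corr)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  reg <- (corr + diag(ridge_eps, p)) / (1 + ridge_eps)
  factor <- tryCatch(
    t(chol(reg)),
    error = function(e) {
      abort(paste0(
        "Cholesky factorization of the regularized LD matrix failed; ",
        "increase `ridge_eps` (currently ", ridge_eps, ")."
      ))
    }
  )
  structure(
    list(
      corr = corr, ridge_eps = ridge_eps, reg = reg, factor = factor,
      snps = as_tibble(snps), source_label = source_label
    ),
    class = "ld_reference"
  )
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf(
    "<ld_reference> %d SNPs, ridge_eps = %g (source: %s)\n",
    nrow(x$corr), x$ridge_eps, x$source_label
  ))
  invisible(x)
}

#' @export
dim.ld_reference <- function(x) dim(x$corr)

#' Estimate a regularized LD matrix from a genotype panel
#'
#' Computes the sample SNP correlation matrix of the standardized dosages
#' and shrinks it toward the identity: `(R + eps * I) / (1 + eps)`, so the
#' diagonal stays 1. The lower Cholesky factor of the regularized matrix is
#' stored for downstream multivariate-normal sampling.
#'
#' @param panel a [genotype_panel()] with at least 2 samples.
#' @param ridge_eps nonnegative ridge weight (default 0.1).
#' @param source_label provenance tag; defaults to the panel source.
#' @return An `ld_reference`.
#' @export
estimate_ld <- function(panel, ridge_eps = 0.1, source_label = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  if (n < 2) abort("at least 2 samples are required to estimate LD.")
  check_scalar(ridge_eps, "ridge_eps", lower = 0)
  # columns are (1/n)-standardized, so crossprod/n is exactly the
  # Pearson correlation matrix with unit diagonal
  corr <- crossprod(panel$dosages) / n
  new_ld_reference(corr, ridge_eps, panel$snps,
                   source_label %||% panel$source)
}

#' Build an LD reference from an explicit correlation matrix
#'
#' Convenience constructor for simulations with a known LD structure
#' (identity, block-exchangeable, ...). SNP metadata is synthesized.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param ridge_eps nonnegative ridge weight (default 0).
#' @param source_label provenance tag.
#' @return An `ld_reference`.
#' @export
ld_from_matrix <- function(corr, ridge_eps = 0, source_label = "matrix") {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8) {
    abort("`corr` must be a symmetric square matrix.")
  }
  if (max(abs(diag(corr) - 1)) > 1e-8) {
    abort("`corr` must have a unit diagonal.")
  }
  new_ld_reference(corr, ridge_eps, default_snps(nrow(corr)), source_label)
}

#' Split a panel into two random halves
#'
#' Partitions the samples into disjoint subsets of sizes `floor(N/2)` and
#' `ceiling(N/2)` sharing the SNP set, for LD reference-panel
#' misspecification experiments. Each half is re-standardized; SNPs that
#' become monomorphic in either half are dropped from both so the halves
#' stay aligned.
#'
#' @param panel a [genotype_panel()] with at least 2 samples.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return A list of two [genotype_panel()] objects.
#' @export
split_panel <- function(panel, seed) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  if (n < 2) abort("at least 2 samples are required to split a panel.")
  with_seed(seed, {
    perm <- sample.int(n)
    i1 <- sort(perm[seq_len(n %/% 2)])
    i2 <- sort(perm[(n %/% 2 + 1):n])
    halves <- lapply(list(i1, i2), function(idx) {
      std <- standardize_columns(panel$dosages[idx, , drop = FALSE],
                                 drop_zero_var = FALSE)
      list(x = std$x, keep = std$keep, idx = idx)
    })
    keep <- halves[[1]]$keep & halves[[2]]$keep
    if (!all(keep)) {
      warn(sprintf(
        "dropped %d SNP(s) monomorphic in one split half", sum(!keep)
      ))
    }
    out <- lapply(seq_along(halves), function(k) {
      h <- halves[[k]]
      genotype_panel(
        h$x[, keep, drop = FALSE],
        panel$snps[keep, , drop = FALSE],
        panel$samples[h$idx],
        source = paste0(panel$source, "_half", k)
      )
    })
    out
  })
}

#' Sample genotypes from an LD reference
#'
#' Draws `n` rows i.i.d. from a mean-zero multivariate normal with
#' covariance equal to the regularized LD matrix (via its stored Cholesky
#' factor), then re-standardizes each column. This is the
#' multivariate-normal genotype approximation used for GWAS and eQTL
#' cohorts in standard mode.
#'
#' @param ld an `ld_reference`.
#' @param n number of individuals to draw.
#' @param seed integer seed.
#' @return A [genotype_panel()] of continuous standardized dosages.
#' @export
sample_genotypes <- function(ld, n, seed) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- check_count(n, "n", lower = 1)
  with_seed(seed, {
    p <- nrow(ld$corr)
    z <- matrix(rnorm(n * p), n, p)
    x <- z %*% t(ld$factor)
    if (n > 1) {
      x <- standardize_columns(x, drop_zero_var = FALSE)$x
    }
    genotype_panel(x, ld$snps, sprintf("mvn%d", seq_len(n)),
                   source = ld$source_label)
  })
}
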