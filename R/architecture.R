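#' Sample a sparse eQTL architecture
#'
#' Draws `n_causal` causal SNP indices uniformly without replacement, gives
#' them i.i.d. standard-normal raw effects, and rescales the vector so the
#' quadratic form against the (regularized) LD matrix equals the target
#' cis-heritability exactly: `b' R b = h2g`. With `h2g = 0` the effect
#' vector is identically zero.
#'
#' @param p number of SNPs; must match the LD reference.
#' @param n_causal number of causal SNPs, between 1 and `p`. A fraction in
#'   (0, 1) is also accepted and converted to `ceiling(n_causal * p)`.
#' @param h2g target cis-heritability of expression, in `[0, 1]`.
#' @param ld an [estimate_ld()] / [ld_from_matrix()] reference of dimension `p`.
#' @param seed integer seed.
#' @return An object of class `eqtl_architecture` with fields `b`,
#'   `causal_mask`, `h2g`, and `snp_id`.
#' @export
sample_eqtl_architecture <- function(p, n_causal, h2g, ld, seed) {
  p <- check_count(p, "p", lower = 1)
  stopifnot(inherits(ld, "ld_reference"))
  if (nrow(ld$corr) != p) abort("`p` must match the LD reference dimension.")
  if (n_causal > 0 && n_causal < 1) n_causal <- ceiling(n_causal * p)
  n_causal <- check_count(n_causal, "n_causal", lower = 1)
  if (n_causal > p) abort("`n_causal` cannot exceed `p`.")
  check_scalar(h2g, "h2g", 0, 1)
  with_seed(seed, {
    b <- numeric(p)
    idx <- sample.int(p, n_causal)
    if (h2g > 0) {
      b[idx] <- rnorm(n_causal)
      q <- as.numeric(t(b) %*% ld$reg %*% b)
      b <- b * sqrt(h2g / q)
    }
    structure(
      list(
        b = b, causal_mask = b != 0, h2g = h2g,
        snp_id = ld$snps$id
      ),
      class = "eqtl_architecture"
    )
  })
}

#' @export
print.eqtl_architecture <- function(x, ...) {
  cat(sprintf(
    "<eqtl_architecture> P = %d, %d causal, h2g = %g\n",
    length(x$b), sum(x$causal_mask), x$h2g
  ))
  invisible(x)
}

#' Derive the expression-to-trait effect for a target mediated variance
#'
#' Under the convention that the genetic expression score `X b` is
#' standardized to unit variance before entering the trait, the causal
#' effect satisfies `alpha^2 = h2ge`. The sign is drawn +/-1 with equal
#' probability, deterministic given the seed.
#'
#' @param h2ge proportion of trait variance explained by genetically
#'   regulated expression, in `[0, 1)`.
#' @param seed integer seed (for the sign).
#' @return A scalar `alpha`.
#' @export
derive_alpha <- function(h2ge, seed) {
  check_scalar(h2ge, "h2ge", 0, 1, upper_open = TRUE)
  with_seed(seed, {
    sgn <- if (runif(1) < 0.5) -1 else 1
    sgn * sqrt(h2ge)
  })
}

new_trait_model <- function(alpha, h2ge, mode, linkage_b = NULL) {
  structure(
    list(alpha = alpha, h2ge = h2ge, mode = mode, linkage_b = linkage_b),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> mode = %s, alpha = %g, h2ge = %g\n",
              x$mode, x$alpha, x$h2ge))
  invisible(x)
}

#' Trait models: causal, null, and linkage
#'
#' `causal_trait()` builds a model where expression causally affects the
#' trait with `alpha^2 = h2ge` (sign random). `null_trait()` sets
#' `alpha = 0`. `sample_linkage_architecture()` builds a horizontal
#' pleiotropy-through-linkage model: direct SNP effects on the trait are
#' drawn by the same sparse procedure as the eQTL effects but from an
#' independent random stream, so the tested gene's eQTLs merely tag the
#' trait signal through LD.
#'
#' @param h2ge trait variance explained (by expression for causal mode; by
#'   the direct SNP effects for linkage mode), in `[0, 1)`.
#' @param seed integer seed.
#' @return A `trait_model`.
#' @export
causal_trait <- function(h2ge, seed) {
  new_trait_model(derive_alpha(h2ge, seed), h2ge, "causal")
}

#' @rdname causal_trait
#' @export
null_trait <- function() {
  new_trait_model(0, 0, "null")
}

#' @rdname causal_trait
#' @param p number of SNPs.
#' @param n_causal number of SNPs with direct trait effects.
#' @param ld LD reference used to scale the direct effects
#'   (`linkage_b' R linkage_b = h2ge`).
#' @param eqtl the gene's [sample_eqtl_architecture()]; carried along for
#'   provenance only -- no constraint ties the two effect vectors.
#' @export
sample_linkage_architecture <- function(p, n_causal, h2ge, ld, eqtl, seed) {
  stopifnot(inherits(eqtl, "eqtl_architecture"))
  check_scalar(h2ge, "h2ge", 0, 1, upper_open = TRUE)
  direct <- sample_eqtl_architecture(p, n_causal, h2ge, ld, seed)
  new_trait_model(0, h2ge, "linkage", linkage_b = direct$b)
}
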