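#' Weight vector objects
#'
#' Per-SNP expression prediction weights on standardized dosages, tagged
#' with the model that produced them and the in-sample fit quality.
#'
#' @param w numeric weights, one per SNP (named by SNP id).
#' @param model_label one of `lasso`, `enet`, `gblup`, `true`, or
#'   `external:<name>`.
#' @param fit_r2 in-sample squared correlation of predicted vs observed
#'   expression (`NA` when not applicable).
#' @param diagnostics list of fit diagnostics.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(w, model_label, fit_r2 = NA_real_,
                          diagnostics = list()) {
  if (!all(is.finite(w))) abort("weights must be finite.")
  structure(
    list(
      w = w, model_label = model_label, fit_r2 = fit_r2,
      all_zero = all(w == 0), diagnostics = diagnostics
    ),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf(
    "<weight_vector> %s: P = %d, %d nonzero, fit R^2 = %s%s\n",
    x$model_label, length(x$w), sum(x$w != 0),
    if (is.na(x$fit_r2)) "NA" else sprintf("%.3f", x$fit_r2),
    if (x$all_zero) " [all-zero]" else ""
  ))
  invisible(x)
}

fit_quality <- function(x, y, w) {
  pred <- as.numeric(x %*% w)
  if (all(w == 0) || sd(pred) == 0) return(0)
  cor(pred, y)^2
}

check_expression_panel <- function(ep, min_n = 10) {
  stopifnot(inherits(ep, "expression_panel"))
  if (nrow(ep$panel$dosages) < min_n) {
    abort(sprintf("at least %d eQTL samples are required.", min_n))
  }
  if (sd(ep$expr) == 0) abort("expression vector has zero variance.")
  invisible(ep)
}

fit_glmnet_weights <- function(ep, mixing, seed, lambda, label) {
  check_expression_panel(ep)
  x <- ep$panel$dosages
  y <- ep$expr
  n <- nrow(x)
  if (is.null(lambda)) {
    foldid <- with_seed(seed, sample(rep_len(1:5, n)))
    cv <- glmnet::cv.glmnet(x, y, alpha = mixing, foldid = foldid,
                            standardize = FALSE)
    lambda_used <- cv$lambda.min
    w <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  } else {
    fit <- glmnet::glmnet(x, y, alpha = mixing, lambda = lambda,
                          standardize = FALSE)
    lambda_used <- lambda
    w <- as.numeric(coef(fit, s = lambda))[-1]
  }
  w <- setNames(w, ep$panel$snps$id)
  weight_vector(w, label, fit_r2 = fit_quality(x, y, w),
                diagnostics = list(lambda = lambda_used, mixing = mixing))
}

#' Fit LASSO expression weights
#'
#' L1-penalized regression of standardized expression on standardized
#' dosages; the penalty is chosen by 5-fold cross-validation with folds
#' seeded for reproducibility (`lambda.min` rule).
#'
#' @param ep an [simulate_expression_panel()] result with >= 10 samples.
#' @param seed integer seed (controls the CV fold assignment only).
#' @param lambda optional fixed penalty, bypassing cross-validation.
#' @return A [weight_vector()] with `model_label = "lasso"`.
#' @export
fit_lasso <- function(ep, seed, lambda = NULL) {
  fit_glmnet_weights(ep, mixing = 1, seed = seed, lambda = lambda,
                     label = "lasso")
}

#' Fit Elastic Net expression weights
#'
#' As [fit_lasso()] with an L1/L2 mixture; `mixing = 1` reproduces the
#' LASSO fit exactly.
#'
#' @inheritParams fit_lasso
#' @param mixing elastic-net mixing parameter in (0, 1]; default 0.5.
#' @return A [weight_vector()] with `model_label = "enet"`.
#' @export
fit_enet <- function(ep, mixing = 0.5, seed, lambda = NULL) {
  check_scalar(mixing, "mixing", 0, 1, lower_open = TRUE)
  fit_glmnet_weights(ep, mixing = mixing, seed = seed, lambda = lambda,
                     label = "enet")
}

# Marginal (restricted) likelihood estimate of cis-h2 under
# expr ~ N(0, sigma2 * (h2 * K + (1 - h2) * I)), K = X X' / P.
# Works through the spectrum of X'X (rank-filtered), so cost is O(P^3).
estimate_h2_reml <- function(x, y) {
  n <- nrow(x)
  p <- ncol(x)
  xtx <- crossprod(x)
  ei <- eigen(xtx, symmetric = TRUE)
  l <- ei$values
  tol <- max(l) * 1e-9
  keep <- l > tol
  d <- l[keep] / p # nonzero eigenvalues of K
  xty <- as.numeric(crossprod(x, y))
  proj <- as.numeric(crossprod(ei$vectors[, keep, drop = FALSE], xty))
  ystar2 <- proj^2 / l[keep]
  yy <- sum(y^2)
  s0 <- max(yy - sum(ystar2), 0)
  k0 <- n - sum(keep)
  nll <- function(h2) {
    v <- h2 * d + (1 - h2)
    rss <- sum(ystar2 / v) + if (k0 > 0) s0 / (1 - h2) else 0
    sigma2 <- rss / n
    0.5 * (n * log(sigma2) + sum(log(v)) + k0 * log(1 - h2))
  }
  opt <- optimize(nll, c(1e-4, 1 - 1e-4))
  list(h2 = opt$minimum, method = "reml")
}

# Haseman-Elston moment estimate: regress off-diagonal y_i y_j on K_ij.
estimate_h2_moments <- function(x, y) {
  n <- nrow(x)
  p <- ncol(x)
  xty <- as.numeric(crossprod(x, y))
  yky <- sum(xty^2) / p
  kdiag <- rowSums(x * x) / p
  num <- yky - sum(kdiag * y^2)
  den <- sum(crossprod(x)^2) / p^2 - sum(kdiag^2)
  list(h2 = num / den, method = "moments")
}

#' Fit GBLUP expression weights
#'
#' Genomic best linear unbiased prediction: the ridge solution
#' `w = (X'X / n + lambda I)^{-1} X'y / n` with penalty
#' `lambda = P (1 - h2) / (n h2)` determined by the estimated
#' cis-heritability. `h2` is estimated by restricted maximum likelihood on
#' the standardized-genotype relatedness matrix (spectral form), floored
#' and capped by `h2_bounds`; a Haseman-Elston method-of-moments estimate
#' is used with a warning if the likelihood optimization fails. Both
#' estimates are recorded in the diagnostics.
#'
#' @param ep an [simulate_expression_panel()] result with >= 10 samples.
#' @param lambda optional fixed penalty (in the `X'X / n` normalization);
#'   `lambda = 0` reproduces the least-squares solution of the normal
#'   equations, very large `lambda` shrinks all weights to zero.
#' @param h2_bounds floor and cap applied to the heritability estimate;
#'   default `c(0.01, 0.99)`.
#' @return A [weight_vector()] with `model_label = "gblup"`.
#' @export
fit_gblup <- function(ep, lambda = NULL, h2_bounds = c(0.01, 0.99)) {
  check_expression_panel(ep)
  x <- ep$panel$dosages
  y <- ep$expr
  n <- nrow(x)
  p <- ncol(x)
  diagnostics <- list()
  if (is.null(lambda)) {
    est <- tryCatch(
      estimate_h2_reml(x, y),
      error = function(e) {
        warn(paste0("REML heritability estimation failed (",
                    conditionMessage(e),
                    "); falling back to method of moments."))
        estimate_h2_moments(x, y)
      }
    )
    h2 <- min(max(est$h2, h2_bounds[1]), h2_bounds[2])
    diagnostics <- list(h2_estimate = est$h2, h2_used = h2,
                        h2_method = est$method,
                        h2_moments = estimate_h2_moments(x, y)$h2)
    lambda <- if (h2 > 0) p * (1 - h2) / (n * h2) else Inf
  }
  diagnostics$lambda <- lambda
  w <- if (!is.finite(lambda)) {
    numeric(p)
  } else {
    xtx <- crossprod(x)
    as.numeric(solve(xtx + diag(n * lambda, p), crossprod(x, y)))
  }
  w <- setNames(w, ep$panel$snps$id)
  weight_vector(w, "gblup", fit_r2 = fit_quality(x, y, w),
                diagnostics = diagnostics)
}

#' Use the true eQTL effects as TWAS weights
#'
#' Passes the simulated causal effect vector through unchanged, bypassing
#' any prediction model; useful as a best-case reference.
#'
#' @param eqtl an [sample_eqtl_architecture()].
#' @return A [weight_vector()] with `model_label = "true"`.
#' @export
true_weights <- function(eqtl) {
  stopifnot(inherits(eqtl, "eqtl_architecture"))
  weight_vector(setNames(eqtl$b, eqtl$snp_id), "true")
}
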