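#' Load an external prediction model plugin
#'
#' Dynamically loads custom prediction code so that independently
#' developed TWAS expression models can be evaluated through the same
#' pipeline as the built-ins. The plugin is an R source file defining a
#' function named `fit` that accepts `(genotypes, expression)` -- the
#' standardized dosage matrix and the standardized expression vector --
#' and returns a numeric weight vector of length `P`. Plugins run
#' in-process; no sandboxing is applied. Two example plugins ship under
#' `system.file("plugins", package = "twasim")`.
#'
#' @param module_path path to an R source file exposing `fit`.
#' @return An object of class `external_predictor`.
#' @export
#' @examples
#' path <- system.file("plugins", "ols_top_snp.R", package = "twasim")
#' pred <- load_external(path)
load_external <- function(module_path) {
  if (!file.exists(module_path)) {
    abort(sprintf("plugin file not found: %s", module_path))
  }
  env <- new.env(parent = globalenv())
  sys.source(module_path, envir = env)
  fn <- get0("fit", envir = env, inherits = FALSE)
  if (!is.function(fn)) {
    abort(sprintf(
      "plugin '%s' does not define a function named `fit`.", module_path
    ))
  }
  stem <- sub("\\.[Rr]$", "", basename(module_path))
  structure(
    list(fit = fn, label = paste0("external:", stem), path = module_path),
    class = "external_predictor"
  )
}

#' @export
print.external_predictor <- function(x, ...) {
  cat(sprintf("<external_predictor> %s (%s)\n", x$label, x$path))
  invisible(x)
}

#' Fit expression weights with an external plugin
#'
#' Calls the plugin's `fit(genotypes, expression)` and validates the
#' returned vector against the plugin contract (numeric, length `P`,
#' finite).
#'
#' @param predictor a [load_external()] result.
#' @param ep an [simulate_expression_panel()] result.
#' @return A [weight_vector()] labelled `external:<stem>`.
#' @export
fit_external <- function(predictor, ep) {
  stopifnot(inherits(predictor, "external_predictor"))
  check_expression_panel(ep, min_n = 2)
  x <- ep$panel$dosages
  y <- ep$expr
  w <- predictor$fit(x, y)
  if (!is.numeric(w) || length(w) != ncol(x)) {
    abort(sprintf(
      "plugin '%s' returned a weight vector of length %d; expected %d.",
      predictor$path, length(w), ncol(x)
    ))
  }
  if (!all(is.finite(w))) {
    abort(sprintf("plugin '%s' returned non-finite weights.",
                  predictor$path))
  }
  w <- setNames(as.numeric(w), ep$panel$snps$id)
  weight_vector(w, predictor$label, fit_r2 = fit_quality(x, y, w),
                diagnostics = list(path = predictor$path))
}
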