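#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an eQTL architecture into a per-SNP table
#'
#' @param x an [sample_eqtl_architecture()] result.
#' @param ... unused.
#' @return A tibble with columns `snp`, `b`, `causal`.
#' @method tidy eqtl_architecture
#' @export
tidy.eqtl_architecture <- function(x, ...) {
  tibble(snp = x$snp_id, b = x$b, causal = x$causal_mask)
}

#' Tidy a weight vector into a per-SNP table
#'
#' @param x a [weight_vector()].
#' @param ... unused.
#' @return A tibble with columns `snp`, `weight`, `model`.
#' @method tidy weight_vector
#' @export
tidy.weight_vector <- function(x, ...) {
  tibble(
    snp = names(x$w) %||% as.character(seq_along(x$w)),
    weight = unname(x$w),
    model = x$model_label
  )
}

#' @rdname tidy.weight_vector
#' @method glance weight_vector
#' @export
glance.weight_vector <- function(x, ...) {
  tibble(
    model = x$model_label, n_snps = length(x$w),
    n_nonzero = sum(x$w != 0), fit_r2 = x$fit_r2, all_zero = x$all_zero
  )
}

#' Tidy an experiment into its per-replicate results
#'
#' @param x a [run_experiment()] result.
#' @param ... unused.
#' @return `tidy()` returns the per-replicate results tibble; `glance()`
#'   the per-model metrics report.
#' @method tidy twas_experiment
#' @export
tidy.twas_experiment <- function(x, ...) {
  as_tibble(x$results)
}

#' @rdname tidy.twas_experiment
#' @method glance twas_experiment
#' @export
glance.twas_experiment <- function(x, ...) {
  as_tibble(x$metrics)
}
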