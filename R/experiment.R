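#' Configure a replicate TWAS simulation experiment
#'
#' Bundles the LD references for the three pipeline stages (GWAS, eQTL,
#' TWAS testing -- any may coincide; the testing stage defaults to the
#' eQTL panel, as in downstream TWAS tools), the sample sizes, the genetic
#' architecture, the simulation mode, and the models to evaluate.
#'
#' @param ld_gwas `ld_reference` used to simulate GWAS data.
#' @param ld_eqtl `ld_reference` for the eQTL reference cohort; defaults
#'   to `ld_gwas`.
#' @param ld_test `ld_reference` for TWAS testing; defaults to `ld_eqtl`.
#' @param n_gwas GWAS sample size (default 100,000).
#' @param n_qtl eQTL cohort size (default 500).
#' @param h2g cis-heritability of expression (default 0.1).
#' @param h2ge proportion of trait variance explained by genetically
#'   regulated expression (default 0.01).
#' @param n_causal number of causal eQTLs (default 1); a fraction in
#'   (0, 1) is interpreted as a fraction of SNPs.
#' @param mode `"fast"` (summary statistics drawn directly from the
#'   LD-parameterized MVN) or `"standard"` (individual-level genotypes and
#'   marginal regression).
#' @param trait_mode `"causal"`, `"null"`, or `"linkage"`.
#' @param models character vector from `lasso`, `enet`, `gblup`, `true`,
#'   `external:<path>`.
#' @param threshold transcriptome-wide significance threshold
#'   (default 2.27e-6, i.e. 0.05 Bonferroni-corrected for ~22,000 genes).
#' @param replicates number of replicate gene simulations.
#' @param enet_mixing elastic-net mixing parameter (default 0.5).
#' @return An object of class `twasim_config`.
#' @export
experiment_config <- function(ld_gwas, ld_eqtl = ld_gwas, ld_test = ld_eqtl,
                              n_gwas = 100000, n_qtl = 500,
                              h2g = 0.1, h2ge = 0.01, n_causal = 1,
                              mode = c("fast", "standard"),
                              trait_mode = c("causal", "null", "linkage"),
                              models = "enet", threshold = 2.27e-6,
                              replicates = 100, enet_mixing = 0.5) {
  mode <- match.arg(mode)
  trait_mode <- match.arg(trait_mode)
  stopifnot(inherits(ld_gwas, "ld_reference"),
            inherits(ld_eqtl, "ld_reference"),
            inherits(ld_test, "ld_reference"))
  ids <- ld_gwas$snps$id
  if (!identical(ids, ld_eqtl$snps$id) || !identical(ids, ld_test$snps$id)) {
    abort("the three LD references must cover the same SNPs in the same order.")
  }
  n_gwas <- check_count(n_gwas, "n_gwas", lower = 1)
  n_qtl <- check_count(n_qtl, "n_qtl", lower = 2)
  check_scalar(h2g, "h2g", 0, 1)
  check_scalar(h2ge, "h2ge", 0, 1, upper_open = TRUE)
  check_scalar(threshold, "threshold", 0, 1, lower_open = TRUE,
               upper_open = TRUE)
  replicates <- check_count(replicates, "replicates", lower = 1)
  known <- c("lasso", "enet", "gblup", "true")
  bad <- models[!(models %in% known | startsWith(models, "external:"))]
  if (length(bad) > 0) {
    abort(paste0("unknown model(s): ", paste(bad, collapse = ", ")))
  }
  if (trait_mode == "causal" && h2ge > 0 && h2g == 0) {
    abort("trait_mode = 'causal' with h2ge > 0 requires h2g > 0.")
  }
  structure(
    list(
      ld_gwas = ld_gwas, ld_eqtl = ld_eqtl, ld_test = ld_test,
      n_gwas = n_gwas, n_qtl = n_qtl, h2g = h2g, h2ge = h2ge,
      n_causal = n_causal, mode = mode, trait_mode = trait_mode,
      models = models, threshold = threshold, replicates = replicates,
      enet_mixing = enet_mixing
    ),
    class = "twasim_config"
  )
}

#' @export
print.twasim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<twasim_config> %s mode, trait = %s, %d replicates\n",
      "  P = %d, n_gwas = %d, n_qtl = %d, h2g = %g, h2ge = %g, ",
      "n_causal = %g\n  models: %s\n  LD: gwas = %s, eqtl = %s, test = %s\n"
    ),
    x$mode, x$trait_mode, x$replicates, nrow(x$ld_gwas$corr), x$n_gwas,
    x$n_qtl, x$h2g, x$h2ge, x$n_causal, paste(x$models, collapse = ", "),
    x$ld_gwas$source_label, x$ld_eqtl$source_label, x$ld_test$source_label
  ))
  invisible(x)
}

config_digest <- function(config) {
  rlang::hash(list(
    p = nrow(config$ld_gwas$corr),
    ld = c(config$ld_gwas$source_label, config$ld_eqtl$source_label,
           config$ld_test$source_label),
    n_gwas = config$n_gwas, n_qtl = config$n_qtl,
    h2g = config$h2g, h2ge = config$h2ge, n_causal = config$n_causal,
    mode = config$mode, trait_mode = config$trait_mode,
    models = config$models, threshold = config$threshold,
    replicates = config$replicates, enet_mixing = config$enet_mixing
  ))
}

# Resolve model labels into fitting closures (external plugins loaded once).
build_predictors <- function(models) {
  lapply(models, function(m) {
    if (m == "true") {
      function(ep, eqtl, seed) true_weights(eqtl)
    } else if (m == "lasso") {
      function(ep, eqtl, seed) fit_lasso(ep, seed = seed)
    } else if (m == "enet") {
      function(ep, eqtl, seed, mixing = 0.5) {
        fit_enet(ep, mixing = mixing, seed = seed)
      }
    } else if (m == "gblup") {
      function(ep, eqtl, seed) fit_gblup(ep)
    } else if (startsWith(m, "external:")) {
      pred <- load_external(sub("^external:", "", m))
      function(ep, eqtl, seed) fit_external(pred, ep)
    }
  })
}

#' Run a replicate TWAS simulation experiment
#'
#' Loops replicates through the full pipeline -- eQTL architecture, trait
#' model, expression reference cohort, prediction models, GWAS (fast or
#' standard mode), TWAS statistic -- and summarizes calibration and power
#' per model. Fully deterministic given the master seed: per-replicate
#' seeds are pre-drawn from the master stream and recorded per row.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @return An object of class `twas_experiment`: a list with `results`
#'   (one tibble row per replicate x model), `metrics`
#'   (a [twas_metrics()] report), `config`, and `seed`.
#' @export
run_experiment <- function(config, seed) {
  stopifnot(inherits(config, "twasim_config"))
  seed <- check_seed(seed)
  p <- nrow(config$ld_gwas$corr)
  digest <- config_digest(config)
  seeds <- with_seed(seed, {
    matrix(sample.int(2147483646L, config$replicates * 6L), ncol = 6L)
  })
  predictors <- build_predictors(config$models)
  needs_panel <- any(config$models != "true")
  rows <- purrr::map(seq_len(config$replicates), function(i) {
    s <- seeds[i, ]
    eqtl <- sample_eqtl_architecture(p, config$n_causal, config$h2g,
                                     config$ld_eqtl, s[1])
    trait <- switch(config$trait_mode,
      null = null_trait(),
      causal = causal_trait(config$h2ge, s[2]),
      linkage = sample_linkage_architecture(p, config$n_causal,
                                            config$h2ge, config$ld_gwas,
                                            eqtl, s[2])
    )
    ep <- if (needs_panel) {
      simulate_expression_panel(config$ld_eqtl, eqtl, config$n_qtl, s[3])
    }
    gwas <- if (config$mode == "fast") {
      simulate_summary_fast(config$ld_gwas, eqtl, trait, config$n_gwas,
                            s[4])
    } else {
      gp <- sample_genotypes(config$ld_gwas, config$n_gwas, s[4])
      y <- simulate_trait(gp, eqtl, trait, s[5])
      marginal_scan(gp, y)
    }
    purrr::map(seq_along(predictors), function(k) {
      seed_k <- (s[6] + 131L * k) %% 2147483646L + 1L
      w <- if (config$models[k] == "enet") {
        predictors[[k]](ep, eqtl, seed_k, mixing = config$enet_mixing)
      } else {
        predictors[[k]](ep, eqtl, seed_k)
      }
      res <- twas_statistic(w, gwas, config$ld_test, replicate_id = i,
                            config_digest = digest)
      res$seed <- s[1]
      res
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows <- dplyr::mutate(
    rows,
    n_qtl = config$n_qtl, h2g = config$h2g, h2ge = config$h2ge,
    mode = config$mode, trait_mode = config$trait_mode,
    ld_eqtl = config$ld_eqtl$source_label,
    .after = "n_gwas"
  )
  metrics <- twas_metrics(rows, threshold = config$threshold)
  structure(
    list(results = rows, metrics = metrics, config = config, seed = seed),
    class = "twas_experiment"
  )
}

#' @export
print.twas_experiment <- function(x, ...) {
  cat(sprintf(
    "<twas_experiment> %d replicates x %d model(s), %s mode, trait = %s\n",
    x$config$replicates, length(x$config$models), x$config$mode,
    x$config$trait_mode
  ))
  print(x$metrics)
  invisible(x)
}
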