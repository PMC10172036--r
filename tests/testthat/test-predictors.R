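make_ep <- function(p = 20, n = 500, h2g = 0.5, n_causal = 1, seed = 1,
                    ld = identity_ld(p)) {
  eq <- sample_eqtl_architecture(p, n_causal, h2g, ld, seed)
  list(eq = eq,
       ep = simulate_expression_panel(ld, eq, n, seed = seed + 1000))
}

test_that("lasso returns all-zero weights above the analytic penalty bound", {
  f <- make_ep(seed = 51)
  x <- f$ep$panel$dosages
  lambda_max <- max(abs(crossprod(x, f$ep$expr))) / nrow(x)
  w <- fit_lasso(f$ep, seed = 1, lambda = lambda_max * 1.01)
  expect_true(w$all_zero)
  expect_identical(w$model_label, "lasso")
})

test_that("lasso recovers a strong single causal eQTL across seeds", {
  hits <- vapply(1:100, function(s) {
    f <- make_ep(n = 1000, h2g = 0.5, seed = s)
    w <- fit_lasso(f$ep, seed = s)
    w$w[which(f$eq$causal_mask)] != 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("glmnet fits are deterministic given the fold seed", {
  f <- make_ep(seed = 52)
  expect_identical(fit_lasso(f$ep, seed = 9)$w, fit_lasso(f$ep, seed = 9)$w)
  expect_identical(fit_enet(f$ep, seed = 9)$w, fit_enet(f$ep, seed = 9)$w)
})

test_that("elastic net at mixing 1 reproduces the lasso", {
  f <- make_ep(seed = 53)
  wl <- fit_lasso(f$ep, seed = 4)
  we <- fit_enet(f$ep, mixing = 1, seed = 4)
  expect_equal(unname(we$w), unname(wl$w), tolerance = 1e-6)
  expect_error(fit_enet(f$ep, mixing = 0, seed = 4), "outside")
})

test_that("elastic net spreads weight across perfectly correlated causals", {
  ld <- exch_ld(2, 1, ridge_eps = 1e-6)
  f <- make_ep(p = 2, n = 500, h2g = 0.4, n_causal = 2, seed = 54, ld = ld)
  w <- fit_enet(f$ep, mixing = 0.5, seed = 5)$w
  expect_lt(abs(w[1] - w[2]), 0.05 * abs(w[1] + w[2]))
})

test_that("null expression rarely yields spurious fit quality", {
  ok <- vapply(1:30, function(s) {
    f <- make_ep(n = 500, h2g = 0, seed = 200 + s)
    fit_enet(f$ep, seed = s)$fit_r2 < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("gblup limits match ridge algebra", {
  f <- make_ep(n = 100, p = 10, seed = 55)
  # infinite shrinkage drives weights to zero
  w_inf <- fit_gblup(f$ep, lambda = 1e9)
  expect_lt(max(abs(w_inf$w)), 1e-6)
  # lambda = 0 reproduces the least-squares normal-equation solution
  w0 <- fit_gblup(f$ep, lambda = 0)
  x <- f$ep$panel$dosages
  ols <- solve(crossprod(x), crossprod(x, f$ep$expr))
  expect_equal(unname(w0$w), as.numeric(ols), tolerance = 1e-8)
})

test_that("gblup concentrates weight on a strong causal eQTL", {
  hits <- vapply(1:40, function(s) {
    f <- make_ep(n = 500, h2g = 0.9, seed = 300 + s)
    w <- fit_gblup(f$ep)
    which.max(abs(w$w)) == which(f$eq$causal_mask)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("gblup heritability estimate tracks the simulated h2g", {
  f <- make_ep(n = 2000, p = 20, h2g = 0.4, n_causal = 5, seed = 56)
  w <- fit_gblup(f$ep)
  expect_identical(w$diagnostics$h2_method, "reml")
  expect_equal(w$diagnostics$h2_estimate, 0.4, tolerance = 0.5)
  expect_true(is.finite(w$diagnostics$h2_moments))
})

test_that("true weights pass the causal effects through unchanged", {
  f <- make_ep(seed = 57)
  w <- true_weights(f$eq)
  expect_identical(unname(w$w), f$eq$b)
  expect_identical(w$model_label, "true")
  eq0 <- sample_eqtl_architecture(20, 1, 0, identity_ld(20), 1)
  expect_true(true_weights(eq0)$all_zero)
})

test_that("TWAS power with true weights bounds fitted models from above", {
  ld <- block_ld_20()
  cfg <- experiment_config(ld, models = c("true", "lasso"),
                           trait_mode = "causal", h2g = 0.05, h2ge = 0.005,
                           n_gwas = 50000, n_qtl = 200, replicates = 150)
  m <- run_experiment(cfg, seed = 58)$metrics
  expect_gte(m$power[m$model == "true"], m$power[m$model == "lasso"])
})

test_that("out-of-sample accuracy rises with eQTL sample size for all models", {
  ld <- identity_ld(20)
  sizes <- c(200, 1000, 5000)
  acc <- matrix(0, 3, 3, dimnames = list(NULL, c("lasso", "enet", "gblup")))
  for (k in seq_along(sizes)) {
    r2 <- vapply(1:40, function(i) {
      s <- 7000 + k * 1000 + i * 7
      eq <- sample_eqtl_architecture(20, 2, 0.1, ld, s)
      ep <- simulate_expression_panel(ld, eq, sizes[k], seed = s + 1)
      holdout <- simulate_expression_panel(ld, eq, 1000, seed = s + 2)
      vapply(list(fit_lasso(ep, seed = s),
                  fit_enet(ep, seed = s),
                  fit_gblup(ep)), function(w) {
        pred <- as.numeric(holdout$panel$dosages %*% w$w)
        if (sd(pred) == 0) 0 else cor(pred, holdout$expr)^2
      }, numeric(1))
    }, numeric(3))
    acc[k, ] <- rowMeans(r2)
  }
  expect_true(all(diff(acc[, "lasso"]) > 0))
  expect_true(all(diff(acc[, "enet"]) > 0))
  expect_true(all(diff(acc[, "gblup"]) > 0))
})

test_that("external plugins honor and enforce the fit contract", {
  path <- system.file("plugins", "ols_top_snp.R", package = "twasim")
  expect_true(nzchar(path))
  pred <- load_external(path)
  expect_identical(pred$label, "external:ols_top_snp")
  f <- make_ep(n = 200, h2g = 0.5, seed = 60)
  w <- fit_external(pred, f$ep)
  expect_length(w$w, 20)
  expect_identical(sum(w$w != 0), 1L)
  expect_identical(w$model_label, "external:ols_top_snp")
  # the bundled sparse-regression stub also conforms
  stub <- load_external(system.file("plugins", "sparse_marginal.R",
                                    package = "twasim"))
  expect_length(fit_external(stub, f$ep)$w, 20)

  # contract violations are named errors
  dir <- withr::local_tempdir()
  no_fit <- file.path(dir, "no_fit.R")
  writeLines("not_fit <- function(x, y) numeric(ncol(x))", no_fit)
  expect_error(load_external(no_fit), "does not define")
  bad_len <- file.path(dir, "bad_len.R")
  writeLines("fit <- function(x, y) numeric(ncol(x) - 1)", bad_len)
  expect_error(fit_external(load_external(bad_len), f$ep), "length")
  nonfinite <- file.path(dir, "nonfinite.R")
  writeLines("fit <- function(x, y) rep(NaN, ncol(x))", nonfinite)
  expect_error(fit_external(load_external(nonfinite), f$ep), "non-finite")
  expect_error(load_external(file.path(dir, "missing.R")), "not found")
})
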