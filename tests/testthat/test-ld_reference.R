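test_that("PLINK round trip preserves genotypes and metadata", {
  counts <- cbind(c(0, 1, 2), c(0, 2, 1))
  prefix <- write_toy_plink(counts)
  panel <- read_plink(prefix)
  expect_equal(dim(panel$dosages), c(3, 2))
  expect_equal(panel$snps$id, c("rs1", "rs2"))
  expect_equal(panel$snps$a1, c("A", "A"))
  expect_equal(panel$snps$pos, c(100L, 200L))
  expect_equal(panel$samples, c("ind1", "ind2", "ind3"))
  # standardization of (0,1,2): mean 0, population variance 1
  expect_equal(panel$dosages[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(colMeans(panel$dosages), c(0, 0), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(colMeans(panel$dosages^2), c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("missing genotypes are mean-imputed and monomorphic SNPs dropped", {
  counts <- cbind(c(0, 1, 2, NA), c(2, 2, 2, 2), c(0, 0, 1, 2))
  prefix <- write_toy_plink(counts)
  expect_warning(panel <- read_plink(prefix), "monomorphic")
  expect_equal(ncol(panel$dosages), 2)
  expect_equal(panel$snps$id, c("rs1", "rs3"))
  # the NA in rs1 was imputed to the observed mean (1), hence maps to 0
  expect_equal(panel$dosages[4, 1], 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(panel$snps$maf > 0 & panel$snps$maf <= 0.5))
})

test_that("read_plink errors on missing files", {
  expect_error(read_plink(file.path(tempdir(), "nope")), "not found")
})

test_that("estimate_ld matches hand-computed correlations", {
  # identical columns: perfect correlation before regularization
  x <- c(-1.2247449, 0, 1.2247449)
  p1 <- genotype_panel(cbind(x, x), default_snps_for_test(2), letters[1:3])
  ld <- estimate_ld(p1, ridge_eps = 0.1)
  expect_equal(ld$corr[1, 2], 1, tolerance = 1e-6)
  # hand Pearson correlation = 0.5
  y <- c(0, -1.2247449, 1.2247449)
  p2 <- genotype_panel(cbind(x, y), default_snps_for_test(2), letters[1:3])
  ld2 <- estimate_ld(p2, ridge_eps = 0)
  expect_equal(ld2$corr[1, 2], 0.5, tolerance = 1e-6)
  expect_error(estimate_ld(genotype_panel(matrix(1, 1, 2),
                                          default_snps_for_test(2), "a")),
               "at least 2")
})

test_that("independent SNPs yield near-identity estimated LD", {
  panel <- sample_genotypes(identity_ld(8), 10000, seed = 11)
  ld <- estimate_ld(panel, ridge_eps = 0)
  off <- ld$corr[upper.tri(ld$corr)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("regularized LD is symmetric, unit-diagonal, and PSD with bounded spectrum", {
  ld <- block_ld_20()
  expect_identical(ld$corr, t(ld$corr))
  expect_equal(diag(ld$corr), rep(1, 20), ignore_attr = TRUE)
  expect_equal(diag(ld$reg), rep(1, 20), ignore_attr = TRUE)
  # factor reproduces the regularized matrix
  expect_lt(norm(ld$factor %*% t(ld$factor) - ld$reg, "F"), 1e-8)
  # convex shrinkage bounds the smallest eigenvalue for a rank-deficient corr
  x <- sample_genotypes(identity_ld(3), 50, seed = 1)$dosages
  sing <- genotype_panel(cbind(x, x[, 1]), default_snps_for_test(4),
                         sprintf("s%d", 1:50))
  for (eps in c(0.05, 0.1, 0.5)) {
    lds <- estimate_ld(sing, ridge_eps = eps)
    ev <- eigen(lds$reg, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), eps / (1 + eps) - 1e-10)
  }
})

test_that("split_panel produces a deterministic disjoint half partition", {
  panel <- generate_panel(fixture_spec(489, 10, within_block_corr = 0.3,
                                       seed = 21))
  halves <- split_panel(panel, seed = 99)
  expect_equal(nrow(halves[[1]]$dosages), 244)
  expect_equal(nrow(halves[[2]]$dosages), 245)
  expect_setequal(c(halves[[1]]$samples, halves[[2]]$samples),
                  panel$samples)
  expect_length(intersect(halves[[1]]$samples, halves[[2]]$samples), 0)
  expect_identical(halves[[1]]$snps$id, halves[[2]]$snps$id)
  again <- split_panel(panel, seed = 99)
  expect_identical(halves[[1]]$samples, again[[1]]$samples)
  expect_identical(halves[[2]]$dosages, again[[2]]$dosages)
  expect_error(split_panel(genotype_panel(matrix(1, 1, 1),
                                          default_snps_for_test(1), "a"),
                           seed = 1),
               "at least 2")
})

test_that("sample_genotypes reproduces the target LD", {
  # independence case
  gp <- sample_genotypes(identity_ld(5), 10000, seed = 5)
  emp <- crossprod(gp$dosages) / 10000
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.05)
  # strong pairwise correlation
  gp2 <- sample_genotypes(exch_ld(2, 0.8), 50000, seed = 6)
  emp2 <- crossprod(gp2$dosages) / 50000
  expect_equal(emp2[1, 2], 0.8, tolerance = 0.02)
  # determinism
  expect_identical(sample_genotypes(identity_ld(3), 50, seed = 7)$dosages,
                   sample_genotypes(identity_ld(3), 50, seed = 7)$dosages)
})

test_that("empirical correlation converges to the regularized LD with n", {
  ld <- estimate_ld(generate_panel(
    fixture_spec(500, 10, block_sizes = c(5, 5), within_block_corr = 0.6,
                 seed = 13)
  ), ridge_eps = 0.1)
  frob <- vapply(c(500, 5000, 50000), function(n) {
    emp <- crossprod(sample_genotypes(ld, n, seed = n)$dosages) / n
    norm(emp - ld$reg, "F")
  }, numeric(1))
  expect_true(all(diff(frob) < 0))
})
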