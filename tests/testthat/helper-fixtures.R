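# Shared in-code fixtures for the test suite. Everything is generated at
# run time; expensive objects are cached per test session.

identity_ld <- function(p, label = "identity") {
  ld_from_matrix(diag(p), ridge_eps = 0, source_label = label)
}

# exchangeable correlation rho with unit diagonal
exch_ld <- function(p, rho, ridge_eps = 0, label = "exchangeable") {
  ld_from_matrix(matrix(rho, p, p) + diag(1 - rho, p), ridge_eps, label)
}

with_null_phenotype <- function(n, seed) withr::with_seed(seed, rnorm(n))

default_snps_for_test <- function(p) {
  tibble::tibble(
    id = paste0("snp", seq_len(p)), chrom = 1L, pos = seq_len(p) * 1000L,
    a0 = "G", a1 = "A", maf = NA_real_
  )
}

.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 400 samples x 20 SNPs, four 5-SNP blocks of moderate LD
block_panel_20 <- function() {
  cached_fixture("block_panel_20", generate_panel(
    fixture_spec(400, 20, block_sizes = rep(5, 4), within_block_corr = 0.7,
                 seed = 3)
  ))
}

block_ld_20 <- function() {
  cached_fixture("block_ld_20", estimate_ld(block_panel_20(), ridge_eps = 0.1))
}

# write a tiny deterministic PLINK triplet of raw counts, return prefix
write_toy_plink <- function(counts, dir = NULL,
                            ids = sprintf("rs%d", seq_len(ncol(counts)))) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  snps <- tibble::tibble(
    id = ids, chrom = 1L, pos = seq_len(ncol(counts)) * 100L,
    a0 = "G", a1 = "A", maf = NA_real_
  )
  prefix <- file.path(dir, "toy")
  write_plink(counts, snps, sprintf("ind%d", seq_len(nrow(counts))), prefix)
  prefix
}
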