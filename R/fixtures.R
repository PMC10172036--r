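#' Specify a synthetic genotype fixture
#'
#' Describes a small diploid genotype panel with block-exchangeable LD,
#' standing in for a real reference panel (e.g. 1000 Genomes EUR) so that
#' simulations and tests run without any download. Haplotypes are latent
#' Gaussians with correlation `within_block_corr` inside each block,
#' dichotomized at the allele-frequency threshold and summed in pairs to
#' diploid genotypes; dichotomization attenuates the realized LD below the
#' latent correlation, which is accepted and measured rather than corrected.
#'
#' @param n_samples number of diploid individuals.
#' @param n_snps number of SNPs.
#' @param block_sizes integer vector summing to `n_snps`; defaults to one
#'   block spanning the locus.
#' @param within_block_corr latent haplotype correlation within a block,
#'   in `[0, 1)`.
#' @param maf_range range of target minor-allele frequencies, within (0, 0.5].
#' @param seed integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples, n_snps, block_sizes = n_snps,
                         within_block_corr = 0.6,
                         maf_range = c(0.05, 0.5), seed = 1) {
  n_samples <- check_count(n_samples, "n_samples", lower = 1)
  n_snps <- check_count(n_snps, "n_snps", lower = 1)
  if (any(block_sizes < 1) || sum(block_sizes) != n_snps) {
    abort("`block_sizes` must be positive and sum to `n_snps`.")
  }
  check_scalar(within_block_corr, "within_block_corr", 0, 1, upper_open = TRUE)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("`maf_range` must be an ordered pair within (0, 0.5].")
  }
  structure(
    list(
      n_samples = n_samples, n_snps = n_snps,
      block_sizes = as.integer(block_sizes),
      within_block_corr = within_block_corr,
      maf_range = as.numeric(maf_range),
      seed = check_seed(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic genotype panel
#'
#' Samples a diploid panel from a [fixture_spec()] and optionally writes it
#' as a PLINK .bed/.bim/.fam triplet. SNPs that come out monomorphic are
#' resampled (new frequency and haplotype noise, shared block factors kept)
#' up to 100 times each before erroring. Deterministic given the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @param prefix optional path stem; when given, the raw allele counts are
#'   written with [write_plink()].
#' @return A [genotype_panel()] (standardized dosages).
#' @export
generate_panel <- function(spec, prefix = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    p <- spec$n_snps
    rho <- spec$within_block_corr
    block <- rep.int(seq_along(spec$block_sizes), spec$block_sizes)
    # shared per-haplotype block factors (2 haplotypes per individual)
    zb <- lapply(1:2, function(h) {
      matrix(rnorm(n * length(spec$block_sizes)), n)
    })
    f <- runif(p, spec$maf_range[1], spec$maf_range[2])
    draw_snp <- function(j, fj) {
      thr <- qnorm(fj)
      h <- vapply(1:2, function(hk) {
        latent <- sqrt(rho) * zb[[hk]][, block[j]] + sqrt(1 - rho) * rnorm(n)
        as.numeric(latent < thr)
      }, numeric(n))
      h[, 1] + h[, 2]
    }
    counts <- matrix(0, n, p)
    for (j in seq_len(p)) {
      g <- draw_snp(j, f[j])
      attempt <- 0
      while (var(g) == 0) {
        attempt <- attempt + 1
        if (attempt == 1) {
          warn(sprintf("resampling monomorphic fixture SNP %d", j))
        }
        if (attempt > 100) {
          abort(sprintf("SNP %d monomorphic after 100 resampling attempts.", j))
        }
        f[j] <- runif(1, spec$maf_range[1], spec$maf_range[2])
        g <- draw_snp(j, f[j])
      }
      counts[, j] <- g
    }
    snps <- tibble(
      id = sprintf("snp%d", seq_len(p)),
      chrom = 1L,
      pos = seq_len(p) * 1000L,
      a0 = "G",
      a1 = "A",
      maf = NA_real_
    )
    samples <- sprintf("sample%d", seq_len(n))
    if (!is.null(prefix)) {
      write_plink(counts, snps, samples, prefix)
    }
    panel_from_counts(counts, snps, samples,
                      source = if (is.null(prefix)) "synthetic"
                               else basename(prefix))
  })
}
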