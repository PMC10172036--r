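#' Genotype panel objects
#'
#' A `genotype_panel` holds an `N x P` matrix of standardized allele dosages
#' (each column mean 0, variance 1 in the 1/n sense) together with SNP
#' metadata and sample identifiers. Dosages count the `.bim` A1 allele.
#'
#' @param dosages numeric matrix of standardized dosages (samples x SNPs).
#' @param snps tibble with columns `id`, `chrom`, `pos`, `a0`, `a1`, `maf`.
#' @param samples character vector of sample identifiers.
#' @param source character provenance tag.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, snps, samples, source = "unknown") {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(snps)) {
    abort("SNP metadata rows must match dosage columns.")
  }
  if (nrow(dosages) != length(samples)) {
    abort("sample identifiers must match dosage rows.")
  }
  colnames(dosages) <- snps$id
  rownames(dosages) <- NULL
  structure(
    list(
      dosages = dosages,
      snps = as_tibble(snps),
      samples = as.character(samples),
      source = source
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d samples x %d SNPs (source: %s)\n",
    nrow(x$dosages), ncol(x$dosages), x$source
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

# Build a standardized panel from raw allele counts (possibly with NAs).
# Missing entries are mean-imputed per SNP; SNPs with zero variance after
# imputation are dropped with a warning. MAF is computed from the imputed
# counts as min(f, 1 - f) where f = mean(count) / 2.
panel_from_counts <- function(counts, snps, samples, source = "unknown") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyNA(counts)) {
    for (j in seq_len(ncol(counts))) {
      miss <- is.na(counts[, j])
      if (any(miss)) counts[miss, j] <- mean(counts[!miss, j])
    }
  }
  f <- colMeans(counts) / 2
  maf <- pmin(f, 1 - f)
  std <- standardize_columns(counts)
  if (!all(std$keep)) {
    dropped <- snps$id[!std$keep]
    warn(sprintf(
      "dropped %d monomorphic SNP(s): %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  snps <- snps[std$keep, , drop = FALSE]
  snps$maf <- maf[std$keep]
  genotype_panel(std$x, snps, samples, source = source)
}

# Default SNP metadata for panels synthesized from an abstract LD matrix.
default_snps <- function(p, prefix = "snp") {
  tibble(
    id = paste0(prefix, seq_len(p)),
    chrom = 1L,
    pos = seq_len(p) * 1000L,
    a0 = "G",
    a1 = "A",
    maf = NA_real_
  )
}
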