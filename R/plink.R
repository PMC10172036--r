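#' Read a PLINK .bed/.bim/.fam triplet
#'
#' Reads a variant-major PLINK binary fileset into a [genotype_panel()].
#' Dosages count the `.bim` A1 allele (column 5); missing genotypes are
#' mean-imputed per SNP before standardization; monomorphic SNPs are
#' dropped with a warning. SNP order follows the `.bim` file.
#'
#' @param prefix path stem; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return A [genotype_panel()] with standardized dosages.
#' @export
#' @examples
#' spec <- fixture_spec(n_samples = 20, n_snps = 4, seed = 1)
#' prefix <- file.path(tempdir(), "toy")
#' generate_panel(spec, prefix = prefix)
#' panel <- read_plink(prefix)
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("PLINK file(s) not found: ", paste(missing, collapse = ", ")))
  }
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a0"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  p <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paths[1], "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    abort("not a variant-major PLINK .bed file (bad magic bytes).")
  }
  raw <- readBin(con, "raw", n = bytes_per_snp * p)
  if (length(raw) != bytes_per_snp * p) {
    abort(".bed size inconsistent with .bim/.fam dimensions.")
  }
  counts <- decode_bed(raw, n, p)
  snps <- tibble(
    id = as.character(bim$id), chrom = bim$chrom, pos = bim$pos,
    a0 = as.character(bim$a0), a1 = as.character(bim$a1), maf = NA_real_
  )
  panel_from_counts(counts, snps, samples = as.character(fam[[2]]),
                    source = basename(prefix))
}

# two-bit PLINK codes -> A1 allele counts: 00 -> 2, 01 -> NA, 10 -> 1, 11 -> 0
decode_bed <- function(raw, n, p) {
  bytes_per_snp <- ceiling(n / 4)
  b <- as.integer(raw)
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = p)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bytes_per_snp, by = 4), ] <-
      matrix(bitwAnd(bitwShiftR(b, 2L * k), 3L), nrow = bytes_per_snp)
  }
  map <- c(2, NA_real_, 1, 0)
  out <- matrix(map[codes + 1L], nrow = 4 * bytes_per_snp, ncol = p)
  out[seq_len(n), , drop = FALSE]
}

#' Write a PLINK .bed/.bim/.fam triplet
#'
#' Writes raw A1-allele counts (values 0/1/2 or NA) in variant-major
#' binary format plus the accompanying text metadata files.
#'
#' @param counts integer matrix (samples x SNPs) of A1 allele counts.
#' @param snps tibble with columns `id`, `chrom`, `pos`, `a0`, `a1`.
#' @param samples character vector of sample identifiers.
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(counts, snps, samples, prefix) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  p <- ncol(counts)
  stopifnot(nrow(snps) == p, length(samples) == n)
  # counts -> two-bit codes: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codes <- matrix(1L, nrow = n, ncol = p)
  codes[!is.na(counts) & counts == 2] <- 0L
  codes[!is.na(counts) & counts == 1] <- 2L
  codes[!is.na(counts) & counts == 0] <- 3L
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, nrow = pad, ncol = p))
  i1 <- seq(1, 4 * bytes_per_snp, by = 4)
  bytes <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1, , drop = FALSE] +
    16L * codes[i1 + 2, , drop = FALSE] +
    64L * codes[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)
  bim <- data.frame(chrom = snps$chrom, id = snps$id, cm = 0,
                    pos = snps$pos, a1 = snps$a1, a0 = snps$a0)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = samples, iid = samples, pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
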