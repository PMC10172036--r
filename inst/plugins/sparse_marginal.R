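# Example twasim plugin: sparse-regression wrapper stub.
# Selects SNPs whose marginal |Z| clears a Bonferroni threshold, then
# solves a joint least-squares fit on the selected set (ridge-stabilized).
# Intended as a template for wrapping sparse regression tools.
fit <- function(genotypes, expression) {
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  xty <- as.numeric(crossprod(genotypes, expression))
  r <- xty / n # marginal correlations (columns standardized)
  z <- r * sqrt(n)
  sel <- which(abs(z) > qnorm(1 - 0.025 / p))
  if (length(sel) == 0) sel <- which.max(abs(z))
  w <- numeric(p)
  xs <- genotypes[, sel, drop = FALSE]
  g <- crossprod(xs) + diag(1e-6 * n, length(sel))
  w[sel] <- as.numeric(solve(g, crossprod(xs, expression)))
  w
}
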