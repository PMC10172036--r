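# Example twasim plugin: ordinary least squares on the top marginal SNP.
# Contract: fit(genotypes, expression) -> numeric weight vector, length P.
fit <- function(genotypes, expression) {
  xty <- as.numeric(crossprod(genotypes, expression))
  j <- which.max(abs(xty))
  w <- numeric(ncol(genotypes))
  w[j] <- xty[j] / sum(genotypes[, j]^2)
  w
}
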