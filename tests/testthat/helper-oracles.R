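# Independent test oracles, deliberately separate from the implementation.

# Two-sided Fisher exact p by full enumeration over tables with fixed
# margins: sum of hypergeometric probabilities no greater than the observed
# table's (with the conventional 1 + 1e-7 relative tolerance for ties).
fisher_enumeration_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pearson chi-square from margins (no correction).
chisq_from_margins <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Crude log-OR and Woolf SE straight from cells.
log_or_woolf <- function(a, b, c, d) {
  list(log_or = log(a * d / (b * c)), se = sqrt(1/a + 1/b + 1/c + 1/d))
}
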