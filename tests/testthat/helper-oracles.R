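# independent brute-force oracles, written directly from the defining
# formulas, used to cross-check the agreement statistics
oracle_pearson <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_kappa <- function(ia, ib, k) {
  n <- length(ia)
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- (i - j)^2 / (k - 1)^2
      o <- sum(ia == i & ib == j) / n
      e <- (sum(ia == i) / n) * (sum(ib == j) / n)
      num <- num + w * o
      den <- den + w * e
    }
  }
  1 - num / den
}
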