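# independent oracles and fixture builders used across the suite

# brute-force Pearson chi-squared statistic, plain loops over (O - E)^2 / E
chisq_oracle <- function(X) {
  N <- sum(X)
  rs <- rowSums(X)
  cs <- colSums(X)
  stat <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      E <- rs[[i]] * cs[[j]] / N
      stat <- stat + (X[i, j] - E)^2 / E
    }
  }
  stat
}

# brute-force adjusted Rand index by enumerating all pairs of observations
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  max_index <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_index == expected) {
    return(if (s10 == 0 && s01 == 0) 1 else 0)
  }
  (s11 - expected) / (max_index - expected)
}

# random integer table guaranteed to have no zero margins
random_table <- function(m, n, max_count = 9) {
  repeat {
    X <- matrix(sample(0:max_count, m * n, replace = TRUE), m, n)
    if (all(rowSums(X) > 0) && all(colSums(X) > 0)) return(X)
  }
}

random_count_matrix <- function(m, n, max_count = 9) {
  count_matrix(random_table(m, n, max_count))
}
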