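# Independent oracles used across the suite. These are deliberately naive
# re-derivations (enumeration / double sums / textbook formulas) kept separate
# from the package's own code paths.

# Quick haplotype builder from token strings.
hap <- function(id, hvri, hvrii = "0", other = "", ...) {
  parseHaplotypeRow(id, hvri, hvrii, other, ...)
}

# Brute-force Pr(K >= k) under the Ewens sampling formula by enumerating all
# integer partitions of n. A configuration with a_j blocks of size j has
# probability n! / theta^(n rising) * prod_j (theta/j)^a_j / a_j!.
ewensTailBrute <- function(n, k_obs, theta) {
  parts <- list()
  recurse <- function(remaining, maxPart, acc) {
    if (remaining == 0) {
      parts[[length(parts) + 1L]] <<- acc
      return(invisible())
    }
    for (j in seq_len(min(remaining, maxPart))) {
      recurse(remaining - j, j, c(acc, j))
    }
  }
  recurse(n, n, integer())
  rising <- prod(theta + 0:(n - 1))
  tot <- 0
  for (p in parts) {
    k <- length(p)
    if (k < k_obs) next
    a <- table(p)
    sizes <- as.integer(names(a))
    prob <- factorial(n) / rising *
      prod((theta / sizes)^as.integer(a) / factorial(as.integer(a)))
    tot <- tot + prob
  }
  tot
}

# Direct double-sum Moran's I.
moranBrute <- function(z, w) {
  n <- length(z)
  zb <- mean(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (z[i] - zb) * (z[j] - zb)
  (n / sum(w)) * num / sum((z - zb)^2)
}

# Textbook Tajima's D, written out independently of the package function.
tajimaBrute <- function(S, mpd, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (mpd - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}
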