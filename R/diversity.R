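# log(exp(a) + exp(b)) without overflow; vector-safe reduction.
.logSumExp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Haplotype (gene) diversity with standard error
#'
#' Nei's unbiased gene diversity \eqn{H = n/(n-1) (1 - \sum p_i^2)} with the
#' sampling variance of Nei (1987, eq. 8.12).
#'
#' @param counts integer vector of haplotype counts (one entry per distinct
#'   haplotype).
#' @return list with \code{H}, \code{SE}, \code{n}, \code{k}.
#' @examples
#' haplotypeDiversity(c(2, 2))  # H = 2/3
#' @export
haplotypeDiversity <- function(counts) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n < 2) stop("need a total sample size of at least 2")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, SE = sqrt(max(V, 0)), n = n, k = length(counts))
}

#' Mean number of pairwise differences, with SE and segregating sites
#'
#' The average of \code{\link{haplotypeDistance}} over all pairs, its total
#' (stochastic + sampling) variance under the no-recombination model of
#' Tajima (1983) as used by the classic population-genetics packages,
#' and the number of segregating variant keys in the window.
#'
#' @param x a \code{\linkS4class{HaplotypeSet}} (n >= 2).
#' @inheritParams distanceMatrix
#' @return list with \code{MPD}, \code{SE}, \code{S}, \code{n}, \code{k}
#'   (distinct haplotypes).
#' @export
meanPairwiseDifferences <- function(x, policy = defaultPolicy(),
                                    region = "HVRI") {
  n <- length(x)
  if (n < 2L) stop("need at least 2 haplotypes")
  d <- distanceMatrix(x, policy, region)
  mpd <- sum(d[upper.tri(d)]) / choose(n, 2)
  V <- (3 * n * (n + 1) * mpd + 2 * (n^2 + n + 3) * mpd^2) /
       (11 * (n^2 - 7 * n + 6))
  list(MPD = mpd, SE = sqrt(max(V, 0)),
       S = segregatingSites(x, policy, region), n = n,
       k = distinctHaplotypes(x, policy, region))
}

#' Tajima's D
#'
#' \deqn{D = (\pi - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} with the standard
#' constants \eqn{a_1 = \sum_{i<n} 1/i}, \eqn{a_2 = \sum_{i<n} 1/i^2},
#' \eqn{b_1 = (n+1)/(3(n-1))}, \eqn{b_2 = 2(n^2+n+3)/(9n(n-1))},
#' \eqn{c_1 = b_1 - 1/a_1}, \eqn{c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2},
#' \eqn{e_1 = c_1/a_1}, \eqn{e_2 = c_2/(a_1^2 + a_2)}.
#'
#' @param S number of segregating sites (>= 1; with S = 0 the statistic is
#'   undefined and \code{NA} is returned).
#' @param mpd mean number of pairwise differences.
#' @param n sample size (>= 4).
#' @return numeric D (or NA when undefined).
#' @export
tajimasD <- function(S, mpd, n) {
  stopifnot(n >= 4)
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (mpd - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, |s(n, 1..n)|, via the
# recurrence |s(m+1,k)| = m |s(m,k)| + |s(m,k-1)| carried in log space.
.logStirling1 <- function(n) {
  ls <- c(0, rep(-Inf, n - 1L))  # |s(1,1)| = 1
  if (n == 1L) return(ls)
  for (m in seq_len(n - 1L)) {
    new <- rep(-Inf, n)
    for (k in seq_len(m + 1L)) {
      a <- if (k <= m) log(m) + ls[k] else -Inf
      b <- if (k >= 2L) ls[k - 1L] else -Inf
      new[k] <- if (a == -Inf) b else if (b == -Inf) a
                else max(a, b) + log1p(exp(-abs(a - b)))
    }
    ls <- new
  }
  ls
}

#' Fu's Fs
#'
#' From the Ewens sampling distribution of the number of distinct haplotypes
#' K in a sample of size n given \eqn{\theta}:
#' \deqn{S' = \Pr(K \ge k_{obs}) = \sum_{k \ge k_{obs}}
#'   |s(n,k)| \theta^k / \theta^{(n)}}
#' with unsigned Stirling numbers of the first kind and the rising factorial
#' \eqn{\theta^{(n)} = \theta(\theta+1)\cdots(\theta+n-1)}, and
#' \eqn{F_s = \ln(S'/(1-S'))}. The sum is carried entirely in log space
#' (the Stirling numbers overflow doubles far below n = 81), using the
#' identity \eqn{\sum_k |s(n,k)|\theta^k = \theta^{(n)}} so that
#' \eqn{F_s = \mathrm{LSE}_{k \ge k_{obs}} - \mathrm{LSE}_{k < k_{obs}}} of
#' the log terms, which is accurate even when \eqn{S'} underflows a double.
#'
#' \eqn{\theta} is conventionally the mean-pairwise-difference estimate.
#' Note that legacy desktop software computed this tail in fixed double
#' precision and saturates near \eqn{F_s \approx -25}; this implementation
#' returns the mathematically exact value, which can be far lower for large
#' samples with many distinct haplotypes.
#'
#' @param n sample size (>= 2).
#' @param k_obs observed number of distinct haplotypes (1..n). With
#'   \code{k_obs = 1}, \eqn{S' = 1} and \code{+Inf} is returned.
#' @param theta positive mutation parameter.
#' @return numeric Fs (possibly \code{Inf} with a warning diagnostic).
#' @examples
#' fusFs(4, 4, 1)  # log(1/23)
#' @export
fusFs <- function(n, k_obs, theta) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n, theta > 0)
  ls <- .logStirling1(n)
  terms <- ls + seq_len(n) * log(theta)
  if (k_obs == 1L) {
    warning("k_obs = 1: S' = 1, Fs is +Inf")
    return(Inf)
  }
  upper <- .logSumExp(terms[k_obs:n])
  lower <- .logSumExp(terms[seq_len(k_obs - 1L)])
  upper - lower
}

# Null distribution of (D, Fs) for n samples conditional on S segregating
# sites, from the fixed-S neutral coalescent. Returns a data.frame.
.neutralNull <- function(n, S, reps, needFs = TRUE) {
  D <- Fs <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- .coalescentCarriers(n, S)
    mpd <- sum(sim$carriers * (n - sim$carriers)) / choose(n, 2)
    D[r] <- tajimasD(S, mpd, n)
    if (needFs) {
      k <- length(unique(sim$signatures))
      Fs[r] <- if (mpd > 0) fusFs(n, k, mpd) else NA_real_
    }
  }
  data.frame(D = D, Fs = if (needFs) Fs else NA_real_)
}

#' Coalescent p-values for Tajima's D and Fu's Fs
#'
#' Simulates \code{reps} neutral constant-size coalescent samples of size
#' \code{n} conditional on the observed number of segregating sites (Hudson's
#' fixed-S conditioning), recomputes both statistics on each replicate, and
#' reports the fraction at least as extreme as observed (one-tailed toward
#' negative values; \code{twoTailed = TRUE} doubles the smaller tail).
#'
#' @param n sample size.
#' @param S observed segregating sites.
#' @param D_obs,Fs_obs observed statistics.
#' @param reps number of coalescent replicates (>= 100).
#' @param seed integer seed for reproducibility.
#' @param twoTailed logical.
#' @return data.frame with rows for D and Fs: \code{p}, \code{SE}
#'   (binomial), \code{reps}.
#' @export
neutralityPValues <- function(n, S, D_obs, Fs_obs, reps = 1000L,
                              seed = NULL, twoTailed = FALSE) {
  stopifnot(reps >= 100L)
  if (!is.null(seed)) set.seed(seed)
  null <- .neutralNull(n, S, reps)
  tail1 <- function(sim, obs) {
    p <- mean(sim <= obs, na.rm = TRUE)
    if (twoTailed) p <- 2 * min(p, mean(sim >= obs, na.rm = TRUE))
    min(p, 1)
  }
  p <- c(D = tail1(null$D, D_obs), Fs = tail1(null$Fs, Fs_obs))
  data.frame(statistic = names(p), p = unname(p),
             SE = sqrt(unname(p) * (1 - unname(p)) / reps),
             reps = reps, stringsAsFactors = FALSE)
}

#' One-row diversity summary for a population
#'
#' Computes the classic control-region summary: sample size, distinct
#' haplotypes, haplotype diversity (SE), mean pairwise differences (SE),
#' nucleotide diversity (SE) over the policy window length, segregating
#' sites, Tajima's D and Fu's Fs with coalescent p-values.
#'
#' @param x a \code{\linkS4class{HaplotypeSet}}.
#' @inheritParams distanceMatrix
#' @param reps coalescent replicates for the p-values (0 skips them).
#' @param seed seed for the p-value simulation.
#' @return one-row data.frame.
#' @export
diversitySummary <- function(x, policy = defaultPolicy(), region = "HVRI",
                             reps = 1000L, seed = 1L) {
  pr <- .profiles(x, policy, region)
  sig <- vapply(pr, function(p) {
    o <- order(names(p)); paste(names(p)[o], p[o], collapse = ";")
  }, "")
  hd <- haplotypeDiversity(as.integer(table(sig)))
  mp <- meanPairwiseDifferences(x, policy, region)
  L <- policy@rangeEnd - policy@rangeStart + 1L - length(policy@excludedPositions)
  D <- tajimasD(mp$S, mp$MPD, mp$n)
  Fs <- if (mp$MPD > 0) fusFs(mp$n, mp$k, mp$MPD) else NA_real_
  pv <- if (reps > 0)
    neutralityPValues(mp$n, mp$S, D, Fs, reps = reps, seed = seed)
  else data.frame(p = c(NA_real_, NA_real_))
  data.frame(n = mp$n, k = mp$k, H = hd$H, H_SE = hd$SE,
             MPD = mp$MPD, MPD_SE = mp$SE,
             pi = mp$MPD / L, pi_SE = mp$SE / L, L = L, S = mp$S,
             D = D, p_D = pv$p[1], Fs = Fs, p_Fs = pv$p[2])
}
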