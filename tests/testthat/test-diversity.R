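test_that("haplotype diversity matches closed forms", {
  # n distinct singletons: H = n/(n-1) * (1 - 1/n) = 1
  expect_equal(haplotypeDiversity(rep(1, 7))$H, 1)
  # counts {2,2}: H = (4/3)(1 - 1/2) = 2/3
  expect_equal(haplotypeDiversity(c(2, 2))$H, 2 / 3)
  expect_error(haplotypeDiversity(1), "at least 2")
  # SE is positive for a polymorphic sample and zero for a monomorphic one
  expect_gt(haplotypeDiversity(c(3, 2, 1))$SE, 0)
  expect_equal(haplotypeDiversity(10)$H, 0)
})

test_that("mean pairwise differences behave on edge cases", {
  a <- hap("a", "129 184 304", "0")
  b <- hap("b", "0", "0")
  m <- meanPairwiseDifferences(c(a, b))
  expect_equal(m$MPD, 3)          # single pair, 3 differing keys
  expect_equal(m$S, 3L)
  same <- c(hap("x", "129", "0"), hap("y", "129", "0"))
  ms <- meanPairwiseDifferences(same)
  expect_equal(ms$MPD, 0)
  expect_equal(ms$S, 1L)          # one variant key, carried by everyone
  expect_equal(distinctHaplotypes(same), 1L)
})

test_that("summary statistics are invariant under sample reordering", {
  set.seed(11)
  sim <- simulateCoalescentSample(15, theta = 4, seed = 11)
  shuffled <- sim[sample(length(sim))]
  expect_equal(meanPairwiseDifferences(sim)$MPD,
               meanPairwiseDifferences(shuffled)$MPD)
  expect_equal(distinctHaplotypes(sim), distinctHaplotypes(shuffled))
})

test_that("Tajima's D matches an independent textbook implementation", {
  expect_equal(tajimasD(0, 1, 10), NA_real_)
  # D = 0 exactly when mpd = S/a1
  a1 <- sum(1 / seq_len(9))
  expect_equal(tajimasD(5, 5 / a1, 10), 0)
  set.seed(42)
  for (r in seq_len(100)) {
    n <- sample(5:200, 1)
    S <- sample(1:80, 1)
    mpd <- stats::runif(1, 0, 15)
    expect_equal(tajimasD(S, mpd, n), tajimaBrute(S, mpd, n),
                 tolerance = 1e-9)
  }
})

test_that("Fu's Fs matches closed forms and brute-force Ewens enumeration", {
  # n=4, k=4, theta=1: S' = 1/24, Fs = log(1/23)
  expect_equal(fusFs(4, 4, 1), log(1 / 23), tolerance = 1e-12)
  expect_warning(f1 <- fusFs(6, 1, 2), "Inf")
  expect_equal(f1, Inf)
  set.seed(7)
  for (r in seq_len(25)) {
    n <- sample(3:8, 1)
    k <- sample(2:n, 1)
    theta <- stats::runif(1, 0.2, 6)
    Sp <- ewensTailBrute(n, k, theta)
    expect_equal(fusFs(n, k, theta), log(Sp / (1 - Sp)), tolerance = 1e-9)
  }
  # log-space evaluation stays finite and negative where doubles underflow
  expect_lt(fusFs(81, 59, 5.9), -50)
  expect_true(is.finite(fusFs(81, 59, 5.9)))
})

test_that("coalescent p-values are deterministic and calibrated", {
  pv1 <- neutralityPValues(20, 8, -1.2, -3, reps = 200, seed = 5)
  pv2 <- neutralityPValues(20, 8, -1.2, -3, reps = 200, seed = 5)
  expect_identical(pv1, pv2)
  expect_true(all(pv1$p >= 0 & pv1$p <= 1))
  # D_obs = 0 sits near the middle of the neutral null
  pv0 <- neutralityPValues(25, 10, 0, 0, reps = 400, seed = 9)
  expect_gt(pv0$p[pv0$statistic == "D"], 0.25)
  expect_lt(pv0$p[pv0$statistic == "D"], 0.75)
})

test_that("the one-row summary is internally consistent", {
  ej <- loadElJadida()
  d <- diversitySummary(ej, reps = 0)
  expect_equal(d$pi, d$MPD / d$L)
  expect_true(d$k <= d$n)
  expect_gte(d$H, 0); expect_lte(d$H, 1)
  expect_gte(d$MPD, 0)
})
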