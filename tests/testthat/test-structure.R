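test_that("Phi-ST is near zero for a random split of one population", {
  set.seed(21)
  pop <- simulateCoalescentSample(24, theta = 5, seed = 21)
  idx <- sample(24, 12)
  phi <- pairwisePhiST(pop[idx], pop[setdiff(1:24, idx)])
  expect_lt(abs(phi), 0.12)
})

test_that("Phi-ST approaches 1 for fixed, distinct populations", {
  a <- do.call(c, lapply(1:12, function(i)
    hap(paste0("a", i), "129 184 304 261 290", "0")))
  b <- do.call(c, lapply(1:12, function(i) hap(paste0("b", i), "0", "0")))
  expect_gt(pairwisePhiST(a, b), 0.9)
})

test_that("degenerate identical monomorphic populations give 0 with warning", {
  a <- c(hap("a1", "129", "0"), hap("a2", "129", "0"))
  b <- c(hap("b1", "129", "0"), hap("b2", "129", "0"))
  expect_warning(phi <- pairwisePhiST(a, b), "identical")
  expect_equal(phi, 0)
})

test_that("AMOVA decomposition is consistent and label-invariant", {
  set.seed(31)
  p1 <- simulateCoalescentSample(10, theta = 4, seed = 31)
  p2 <- simulateCoalescentSample(10, theta = 4, seed = 32)
  p3 <- simulateCoalescentSample(10, theta = 4, seed = 33)
  res <- amova(list(x = p1, y = p2, z = p3))
  expect_equal(res$percentAmong + res$percentWithin, 100, tolerance = 1e-6)
  relabeled <- amova(list(q = p3, r = p1, s = p2))
  expect_equal(res$percentAmong, relabeled$percentAmong, tolerance = 1e-9)
  # pairwise AMOVA equals the pairwise Phi-ST decomposition
  ab <- amova(list(a = p1, b = p2))
  phi <- pairwisePhiST(p1, p2)
  sa <- max(ab$sigmaAmong, 0)
  expect_equal(phi, ab$sigmaAmong / (ab$sigmaAmong + ab$sigmaWithin),
               tolerance = 1e-9)
  # identical populations: essentially nothing among groups
  dup <- amova(list(a = p1, b = p1))
  expect_lt(dup$percentAmong, 1e-9)
  # singleton populations are excluded with a warning
  expect_warning(amova(list(a = p1, b = p2, tiny = p3[1])), "size 1")
})

test_that("no-structure simulations have near-zero mean percent among", {
  set.seed(41)
  vals <- replicate(40, {
    pool <- simulateCoalescentSample(24, theta = 4)
    idx <- sample(rep(1:4, each = 6))
    res <- suppressWarnings(
      amova(split(seq_len(24), idx) |>
              lapply(function(i) pool[i])))
    res$percentAmong
  })
  # percentAmong is truncated at 0, so its null mean is small but positive
  expect_lt(mean(vals), 8)
})

test_that("the permutation test is reproducible and well calibrated", {
  set.seed(51)
  pop <- simulateCoalescentSample(20, theta = 5, seed = 51)
  a <- pop[1:10]; b <- pop[11:20]
  t1 <- phistPermutationTest(a, b, reps = 200, seed = 3)
  t2 <- phistPermutationTest(a, b, reps = 200, seed = 3)
  expect_identical(t1, t2)
  expect_gt(t1$p, 0.05)  # no real structure
  expect_match(t1$formatted, "^p value = ")
  # strong structure: p reported as 0.000 +- 0.000
  x <- do.call(c, lapply(1:10, function(i)
    hap(paste0("x", i), "129 184 304 261 290", "0")))
  y <- do.call(c, lapply(1:10, function(i) hap(paste0("y", i), "0", "0")))
  ts <- phistPermutationTest(x, y, reps = 500, seed = 4)
  expect_lt(ts$p, 0.01)
  expect_match(ts$formatted, "0.00[0-9] \\+- 0.000")
})

test_that("Bonferroni flags compare p to alpha/m", {
  p <- c(0.001, 0.02, 0.04, 0.6)
  expect_equal(bonferroniFlags(p, 0.05), p < 0.05 / 4)
})
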