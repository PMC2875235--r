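test_that("rho is the multiplicity-weighted mean mutation count", {
  expect_equal(rhoStatistic(cladeCluster("x", c(1, 1, 2, 0))), 1)
  expect_equal(rhoStatistic(cladeCluster("x", c(0, 0, 0))), 0)
  expect_equal(rhoStatistic(cladeCluster("x", 3)), 3)
  # invariant to tip order; doubling multiplicities changes nothing
  cl1 <- cladeCluster("x", c(2, 5, 1), c(1, 2, 3))
  cl2 <- cladeCluster("x", c(1, 5, 2), c(3, 2, 1))
  expect_equal(rhoStatistic(cl1), rhoStatistic(cl2))
  cl3 <- cladeCluster("x", c(2, 5, 1), 2 * c(1, 2, 3))
  expect_equal(rhoStatistic(cl1), rhoStatistic(cl3))
  # shared tip haplotypes counted once, while N keeps the multiplicities
  expect_equal(rhoStatistic(cladeCluster("x", c(2, 2), c(3, 1)),
                            sharedTipsOnce = TRUE), 1)
})

test_that("sigma follows the branch-weighted Poisson form", {
  star <- cladeCluster("s", c(1, 1, 2, 0))
  expect_equal(rhoSigma(star), sqrt(4) / 4)          # star closed form
  expect_equal(rhoSigma(cladeCluster("t", 3)), sqrt(3))
  expect_equal(rhoSigma(cladeCluster("z", c(0, 0))), 0)
  # explicit branch table: sigma = sqrt(sum((n_b/N)^2 l_b))
  cl <- cladeCluster("b", c(3, 3, 1),
                     branches = data.frame(nTips = c(2, 1, 1, 1),
                                           length = c(2, 1, 1, 1)))
  expect_equal(rhoSigma(cl), sqrt((2 / 3)^2 * 2 + 3 * (1 / 3)^2))
  expect_error(rhoSigma(cladeCluster("n", c(1, 2)), star = FALSE), "star")
  # branch bookkeeping must reconcile with the tip counts
  expect_error(cladeCluster("bad", c(1, 1),
                            branches = data.frame(nTips = 2, length = 5)),
               "bookkeeping")
})

test_that("ages are rho times the calibration", {
  cal <- clockCalibration()
  expect_equal(unname(rhoAge(1, 0.5, cal)), c(3624, 1812))
  expect_equal(unname(rhoAge(0, 0, cal)["years"]), 0)
  # user-supplied transform hook applies to both estimate and sd
  a <- rhoAge(2, 1, cal, transform = function(y) y / 2)
  expect_equal(unname(a), c(3624, 1812))
  expect_error(clockCalibration(-1), "positive")
})

test_that("simulated star clades have the stated mutation rate", {
  set.seed(61)
  cl <- simulateClade(4000, trueAgeYears = 3624, topology = "star")
  expect_equal(mean(cl@tips$count), 1, tolerance = 0.1)
  cl0 <- simulateClade(50, trueAgeYears = 0, topology = "star")
  expect_true(all(cl0@tips$count == 0))
  expect_equal(rhoStatistic(cl0), 0)
})

test_that("rho recovers the true age of simulated coalescent clades", {
  set.seed(71)
  reps <- 150
  ages <- vapply(seq_len(reps), function(r) {
    cl <- simulateClade(12, trueAgeYears = 10000, topology = "random")
    unname(rhoAge(rhoStatistic(cl), rhoSigma(cl))["years"])
  }, 0)
  se <- sd(ages) / sqrt(reps)
  expect_lt(abs(mean(ages) - 10000), 2 * se + 1e-9)
})

test_that("clade tables read into clusters", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("clade\tid\tcount\tmultiplicity",
               "A\ta1\t1\t2", "A\ta2\t3\t1", "B\tb1\t0\t5"), tmp)
  cls <- readCladeTable(tmp)
  expect_equal(names(cls), c("A", "B"))
  expect_equal(rhoStatistic(cls$A), 5 / 3)
  expect_equal(rhoStatistic(cls$B), 0)
})
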