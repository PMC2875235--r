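test_that("great-circle distances behave like a haversine on r = 6371 km", {
  expect_equal(greatCircleDistance(10, 20, 10, 20), 0)
  # antipodal points on the equator: half the circumference
  expect_equal(greatCircleDistance(0, 0, 0, 180), pi * 6371,
               tolerance = 1e-6)
  expect_equal(greatCircleDistance(12, -4, -33, 50),
               greatCircleDistance(-33, 50, 12, -4))
})

test_that("IDW reproduces the two-point hand computation", {
  # z = 0.2 at d = 1 km, z = 0.4 at d = 2 km, p = 2 -> 0.24
  # place the target at the origin on the equator; 1 degree ~ 111.19 km
  kmPerDeg <- pi * 6371 / 180
  pts <- data.frame(lat = 0, lon = c(1, 2) / kmPerDeg, value = c(0.2, 0.4))
  surf <- idwInterpolate(pts, power = 2, gridLat = 0, gridLon = 0)
  expect_equal(surf@grid$value, 0.24, tolerance = 1e-9)
})

test_that("IDW is exact at sample points, bounded, and scale-equivariant", {
  set.seed(81)
  pts <- data.frame(lat = runif(6, 0, 20), lon = runif(6, 0, 20),
                    value = runif(6))
  surf <- idwInterpolate(pts, gridLat = pts$lat, gridLon = pts$lon)
  g <- surf@grid
  for (i in seq_len(nrow(pts))) {
    at <- g$value[abs(g$lat - pts$lat[i]) < 1e-12 &
                  abs(g$lon - pts$lon[i]) < 1e-12]
    expect_equal(at, pts$value[i])
  }
  expect_true(all(g$value >= min(pts$value) - 1e-12))
  expect_true(all(g$value <= max(pts$value) + 1e-12))
  # constant field interpolates to the constant
  ptsC <- transform(pts, value = 0.3)
  surfC <- idwInterpolate(ptsC, gridLat = c(2, 9), gridLon = c(1, 14))
  expect_true(all(abs(surfC@grid$value - 0.3) < 1e-12))
  # scale equivariance
  surf2 <- idwInterpolate(transform(pts, value = 3 * value),
                          gridLat = c(3, 7), gridLon = c(2, 11))
  surf1 <- idwInterpolate(pts, gridLat = c(3, 7), gridLon = c(2, 11))
  expect_equal(surf2@grid$value, 3 * surf1@grid$value, tolerance = 1e-12)
})

test_that("Moran's I matches the brute-force double sum", {
  set.seed(91)
  for (r in seq_len(30)) {
    n <- sample(4:12, 1)
    z <- rnorm(n)
    w <- matrix(rbinom(n * n, 1, 0.5), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    if (sum(w) == 0) next
    expect_equal(moransI(z, w), moranBrute(z, w), tolerance = 1e-12)
  }
  # checkerboard on a bipartite unlike-neighbour graph: I = -1
  z <- c(1, -1, 1, -1)
  w <- outer(z, z, function(a, b) as.numeric(a != b))
  diag(w) <- 0
  expect_equal(moransI(z, w), -1)
  expect_error(moransI(c(1, 2, 3), matrix(0, 3, 3)), "zero")
  expect_warning(i0 <- moransI(c(1, 1, 1), 1 - diag(3)), "variance")
  expect_true(is.na(i0))
})

test_that("Moran's I has permutation expectation -1/(n-1)", {
  set.seed(101)
  n <- 9
  z <- rnorm(n)
  w <- 1 * (as.matrix(dist(cbind(runif(n), runif(n)))) < 0.5)
  diag(w) <- 0
  perm <- replicate(3000, moransI(sample(z), w))
  expect_equal(mean(perm), -1 / (n - 1), tolerance = 0.02)
})

test_that("correlogram classes partition the pairs", {
  pts <- generateClinalPopulations(noiseSD = 0.05, seed = 5)
  cg <- moranCorrelogram(pts, nClasses = 14, reps = 99, seed = 6)
  cl <- cg@classes
  n <- nrow(pts)
  expect_equal(sum(cl$nPairs), choose(n, 2))
  # classes are ordered and non-overlapping
  expect_true(all(diff(cl$meanDist) > 0))
  expect_true(all(cl$lower[-1] >= cl$upper[-nrow(cl)] - 1e-9))
  # deterministic under a fixed seed
  cg2 <- moranCorrelogram(pts, nClasses = 14, reps = 99, seed = 6)
  expect_identical(cg@classes, cg2@classes)
  # too few pairs: classes reduced with a warning
  expect_warning(moranCorrelogram(pts[1:4, ], nClasses = 14, reps = 49),
                 "reducing")
})

test_that("cline detection distinguishes gradients from noise", {
  cline <- generateClinalPopulations(gLat = -0.025, intercept = 1,
                                     noiseSD = 0.01, seed = 7)
  expect_true(detectCline(moranCorrelogram(cline, reps = 199, seed = 8)))
  flat <- generateClinalPopulations(noiseSD = 0, seed = 9)  # constant field
  expect_false(detectCline(suppressWarnings(
    moranCorrelogram(flat, reps = 99, seed = 10))))
})
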