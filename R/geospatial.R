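#' Great-circle distance between points, in km
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return numeric distance(s) in km.
#' @export
greatCircleDistance <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}

# Pairwise km distance matrix for a points data.frame (lat, lon).
.geoDistMatrix <- function(points) {
  n <- nrow(points)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- greatCircleDistance(points$lat[i], points$lon[i],
                                  points$lat, points$lon)
  }
  (d + t(d)) / 2
}

#' Inverse-distance-weighted interpolation of a frequency surface
#'
#' \eqn{\hat z(x) = \sum_i d_i^{-p} z_i / \sum_i d_i^{-p}}; a grid cell
#' coincident with a sample point takes that sample's value exactly, and
#' every interpolated value lies within the range of the input values.
#' Distances are great-circle km on the unprojected lat/lon grid.
#'
#' @param points data.frame with columns \code{lat}, \code{lon},
#'   \code{value} (and optionally \code{population}).
#' @param power IDW power (default 2).
#' @param gridLat,gridLon grid axis coordinates; default a 25 x 25 grid over
#'   the bounding box of the points.
#' @return a \code{\linkS4class{FrequencySurface}}.
#' @examples
#' pts <- data.frame(lat = c(0, 0), lon = c(1, 2), value = c(0.2, 0.4))
#' surf <- idwInterpolate(pts, gridLat = 0, gridLon = 0)
#' @export
idwInterpolate <- function(points, power = 2,
                           gridLat = NULL, gridLon = NULL) {
  stopifnot(nrow(points) >= 1L, power > 0)
  if (is.null(gridLat))
    gridLat <- seq(min(points$lat), max(points$lat), length.out = 25)
  if (is.null(gridLon))
    gridLon <- seq(min(points$lon), max(points$lon), length.out = 25)
  grid <- expand.grid(lon = gridLon, lat = gridLat)
  z <- vapply(seq_len(nrow(grid)), function(i) {
    d <- greatCircleDistance(grid$lat[i], grid$lon[i],
                             points$lat, points$lon)
    hit <- which(d < 1e-9)
    if (length(hit)) return(points$value[hit[1L]])
    w <- d^(-power)
    sum(w * points$value) / sum(w)
  }, 0)
  new("FrequencySurface",
      grid = data.frame(lon = grid$lon, lat = grid$lat, value = z),
      power = power, points = as.data.frame(points))
}

#' Export a frequency surface as a gridded CSV
#' @param surface a \code{\linkS4class{FrequencySurface}}.
#' @param path output path.
#' @export
writeSurface <- function(surface, path) {
  utils::write.csv(surface@grid, path, row.names = FALSE)
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = (n/W) \sum_{ij} w_{ij} (z_i - \bar z)(z_j - \bar z) /
#'   \sum_i (z_i - \bar z)^2}
#' for a symmetric zero-diagonal weight matrix with total weight W.
#'
#' @param values numeric vector (>= 3 values).
#' @param weights symmetric numeric matrix, zero diagonal, some positive
#'   entry.
#' @return numeric I, or NA with a warning when the values have zero
#'   variance.
#' @export
moransI <- function(values, weights) {
  n <- length(values)
  stopifnot(n >= 3L, nrow(weights) == n, ncol(weights) == n)
  if (any(abs(weights - t(weights)) > 1e-12) || any(diag(weights) != 0))
    stop("weights must be symmetric with a zero diagonal")
  W <- sum(weights)
  if (W <= 0) stop("weights sum to zero")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) {
    warning("zero variance in values; Moran's I undefined")
    return(NA_real_)
  }
  (n / W) * as.numeric(t(z) %*% weights %*% z) / denom
}

#' Moran's I distance-class correlogram
#'
#' Pair distances are split into \code{nClasses} equal-count classes; within
#' each class Moran's I is computed with binary weights (1 when the pair's
#' distance falls in the class) and a permutation p-value from \code{reps}
#' random relabelings of the values.
#'
#' @param points data.frame with columns \code{lat}, \code{lon},
#'   \code{value}.
#' @param nClasses number of distance classes (default 14); reduced with a
#'   warning when there are too few pairs.
#' @param reps permutation replicates per class.
#' @param seed optional integer seed (the correlogram is deterministic under
#'   a fixed seed).
#' @return a \code{\linkS4class{Correlogram}}.
#' @export
moranCorrelogram <- function(points, nClasses = 14L, reps = 199L,
                             seed = NULL) {
  n <- nrow(points)
  stopifnot(n >= 3L)
  if (!is.null(seed)) set.seed(seed)
  d <- .geoDistMatrix(points)
  pd <- d[upper.tri(d)]
  if (length(pd) < nClasses) {
    warning("fewer pairs than classes; reducing to ", length(pd), " classes")
    nClasses <- length(pd)
  }
  qs <- stats::quantile(pd, probs = seq(0, 1, length.out = nClasses + 1L),
                        type = 1)
  qs[1L] <- -Inf  # every pair lands in exactly one class
  cls <- cut(pd, breaks = unique(qs), include.lowest = TRUE)
  # map back onto the matrix
  classIdx <- matrix(0L, n, n)
  classIdx[upper.tri(classIdx)] <- as.integer(cls)
  classIdx <- classIdx + t(classIdx)
  z <- points$value
  levelsUsed <- sort(unique(as.integer(cls)))
  rows <- lapply(levelsUsed, function(k) {
    w <- (classIdx == k) * 1
    diag(w) <- 0
    I <- suppressWarnings(moransI(z, w))
    if (is.na(I)) {
      p <- NA_real_
    } else {
      perm <- vapply(seq_len(reps), function(r)
        moransI(sample(z), w), 0)
      p <- (sum(abs(perm) >= abs(I) - 1e-12) + 1) / (reps + 1)
    }
    inCls <- classIdx == k & upper.tri(classIdx)
    data.frame(class = k,
               lower = min(d[inCls]), upper = max(d[inCls]),
               meanDist = mean(d[inCls]), nPairs = sum(inCls),
               I = I, p = p)
  })
  new("Correlogram", classes = do.call(rbind, rows), nPoints = as.integer(n),
      reps = as.integer(reps))
}

#' Diagnose a frequency cline from a correlogram
#'
#' A cline is called when (i) the first distance class has positive,
#' significant Moran's I, (ii) the rank correlation of I against class index
#' is negative and significant, and (iii) at least one of the last
#' \code{lastK} classes has negative I. All three thresholds are
#' configurable; a correlogram with undefined I (zero-variance values)
#' yields \code{FALSE}.
#'
#' @param correlogram a \code{\linkS4class{Correlogram}}.
#' @param alpha significance threshold for (i) and (ii).
#' @param lastK how many terminal classes to scan for negative I.
#' @return logical.
#' @export
detectCline <- function(correlogram, alpha = 0.05, lastK = 3L) {
  cl <- correlogram@classes
  if (anyNA(cl$I)) return(FALSE)
  firstOK <- cl$I[1L] > 0 && cl$p[1L] < alpha
  if (!firstOK) return(FALSE)
  ct <- suppressWarnings(
    stats::cor.test(cl$I, seq_len(nrow(cl)), method = "spearman"))
  trendOK <- !is.na(ct$estimate) && ct$estimate < 0 && ct$p.value < alpha
  tailOK <- any(utils::tail(cl$I, lastK) < 0)
  firstOK && trendOK && tailOK
}
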