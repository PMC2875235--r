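# Simulate a neutral constant-size coalescent genealogy for n tips and place
# mutations on it. Returns per-mutation carrier counts and per-tip haplotype
# signatures without materialising sequences (used by the p-value machinery).
# mode: fixed S (exactly S mutations, multinomial on branches by length) or
# fixed theta (Poisson theta/2 per unit branch length; time in units of 2N).
.coalescentCarriers <- function(n, S = NULL, theta = NULL) {
  stopifnot(n >= 2)
  tipsets <- as.list(seq_len(n))
  lens <- numeric(n)
  edgeTips <- vector("list", 2L * (n - 1L))
  edgeLen <- numeric(2L * (n - 1L))
  nextEdge <- 1L
  while (length(tipsets) > 1L) {
    k <- length(tipsets)
    t <- stats::rexp(1L, rate = k * (k - 1) / 2)
    lens <- lens + t
    pair <- sample.int(k, 2L)
    for (p in pair) {
      edgeTips[[nextEdge]] <- tipsets[[p]]
      edgeLen[nextEdge] <- lens[p]
      nextEdge <- nextEdge + 1L
    }
    tipsets <- c(tipsets[-pair], list(c(tipsets[[pair[1L]]],
                                        tipsets[[pair[2L]]])))
    lens <- c(lens[-pair], 0)
  }
  total <- sum(edgeLen)
  nmut <- if (!is.null(S)) {
    if (S == 0L) integer(length(edgeLen))
    else as.integer(stats::rmultinom(1L, S, edgeLen / total))
  } else {
    stats::rpois(length(edgeLen), theta / 2 * edgeLen)
  }
  hit <- which(nmut > 0L)
  carriers <- rep(vapply(edgeTips[hit], length, 1L), nmut[hit])
  sig <- rep("", n)
  for (e in hit) {
    idx <- edgeTips[[e]]
    sig[idx] <- paste(sig[idx], e, nmut[e])
  }
  list(carriers = carriers, signatures = sig,
       edgeTips = edgeTips, nmut = nmut)
}

#' Simulate a neutral coalescent haplotype sample
#'
#' Draws a standard constant-size neutral coalescent genealogy and places
#' mutations under the infinite-sites model onto distinct positions sampled
#' uniformly from the window: in fixed-S mode exactly \code{S} mutations are
#' placed multinomially on branches proportional to length; in fixed-theta
#' mode each branch receives Poisson(\eqn{\theta/2 \times} length) mutations
#' (time in units of 2N generations, so the expected pairwise difference
#' equals \eqn{\theta}). Variants are emitted as HVRI transition tokens.
#'
#' @param n number of haplotypes (>= 2).
#' @param S fixed number of segregating sites (exclusive with \code{theta}).
#' @param theta scaled mutation rate (exclusive with \code{S}).
#' @param window length-2 integer vector of rCRS positions to draw sites from.
#' @param seed optional integer seed.
#' @param population population label for the output.
#' @return a \code{\linkS4class{HaplotypeSet}} of length \code{n}.
#' @examples
#' sim <- simulateCoalescentSample(10, S = 5, seed = 1)
#' segregatingSites(sim)  # 5 by construction
#' @export
simulateCoalescentSample <- function(n, S = NULL, theta = NULL,
                                     window = c(16024L, 16360L), seed = NULL,
                                     population = "sim") {
  if (is.null(S) == is.null(theta))
    stop("give exactly one of S (fixed-S mode) or theta (fixed-theta mode)")
  if (!is.null(seed)) set.seed(seed)
  sim <- .coalescentCarriers(n, S = S, theta = theta)
  nSites <- sum(sim$nmut)
  span <- seq.int(window[1L], window[2L])
  if (nSites > length(span))
    stop("window too small for ", nSites, " infinite-sites mutations")
  pos <- sample(span, nSites)
  variants <- NULL
  if (nSites > 0L) {
    edgeOf <- rep(seq_along(sim$nmut), sim$nmut)
    rows <- lapply(seq_len(nSites), function(m) {
      tips <- sim$edgeTips[[edgeOf[m]]]
      data.frame(sample_id = paste0("s", tips), region = "HVRI",
                 position = pos[m], insertIndex = 0L,
                 kind = "substitution", alleles = "",
                 stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, rows)
  } else {
    variants <- data.frame(sample_id = character(), region = character(),
                           position = integer(), insertIndex = integer(),
                           kind = character(), alleles = character(),
                           stringsAsFactors = FALSE)
  }
  new("HaplotypeSet", sampleID = paste0("s", seq_len(n)),
      population = rep(population, n),
      haplogroup = rep(NA_character_, n),
      codingTyped = rep(FALSE, n), variants = variants)
}

#' Construct a clade cluster
#'
#' @param name clade label.
#' @param counts integer vector: mutations from the ancestral haplotype to
#'   each tip.
#' @param multiplicities number of samples sharing each tip haplotype.
#' @param branches optional data.frame with columns \code{nTips},
#'   \code{length} describing the within-clade tree; omitted under the star
#'   assumption.
#' @param ids optional tip labels.
#' @return a \code{\linkS4class{CladeCluster}}.
#' @export
cladeCluster <- function(name, counts, multiplicities = rep(1L, length(counts)),
                         branches = NULL, ids = paste0("t", seq_along(counts))) {
  if (is.null(branches))
    branches <- data.frame(nTips = integer(), length = numeric())
  new("CladeCluster", name = name,
      tips = data.frame(id = ids, count = as.numeric(counts),
                        multiplicity = as.numeric(multiplicities),
                        stringsAsFactors = FALSE),
      branches = branches)
}

#' Simulate a mutation-annotated clade of known age
#'
#' Generates a clade whose most recent common ancestor lived
#' \code{trueAgeYears} ago and sprinkles mutations as a Poisson process at
#' the calibration rate. Under \code{topology = "star"} every tip hangs
#' directly off the ancestor; under \code{"random"} an ultrametric
#' coalescent-shaped genealogy is drawn and rescaled so the root sits at the
#' true age, and the branch table records descendant-tip counts and observed
#' mutation counts per branch.
#'
#' @param nTips number of tips.
#' @param trueAgeYears age of the clade ancestor in years.
#' @param cal a \code{\linkS4class{ClockCalibration}}.
#' @param topology \code{"star"} or \code{"random"}.
#' @param seed optional integer seed.
#' @return a \code{\linkS4class{CladeCluster}}.
#' @export
simulateClade <- function(nTips, trueAgeYears,
                          cal = clockCalibration(),
                          topology = c("star", "random"), seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(trueAgeYears >= 0, nTips >= 1)
  if (!is.null(seed)) set.seed(seed)
  rate <- 1 / cal@yearsPerMutation
  if (topology == "star" || nTips == 1L) {
    counts <- stats::rpois(nTips, trueAgeYears * rate)
    return(cladeCluster("sim-star", counts,
                        branches = data.frame(nTips = rep(1L, nTips),
                                              length = as.numeric(counts))))
  }
  # draw an ultrametric coalescent-shaped genealogy, keeping edge tipsets
  # and lengths, then rescale so the root depth equals the true age
  tipsets <- as.list(seq_len(nTips)); acc <- numeric(nTips)
  edgeTips <- list(); edgeLen <- numeric()
  while (length(tipsets) > 1L) {
    k <- length(tipsets)
    t <- stats::rexp(1L, rate = k * (k - 1) / 2)
    acc <- acc + t
    pair <- sample.int(k, 2L)
    for (p in pair) {
      edgeTips <- c(edgeTips, tipsets[p])
      edgeLen <- c(edgeLen, acc[p])
    }
    tipsets <- c(tipsets[-pair], list(c(tipsets[[pair[1L]]],
                                        tipsets[[pair[2L]]])))
    acc <- c(acc[-pair], 0)
  }
  rootDepth <- sum(vapply(seq_along(edgeTips), function(e)
    if (1L %in% edgeTips[[e]]) edgeLen[e] else 0, 0))
  scale <- trueAgeYears / rootDepth
  mut <- stats::rpois(length(edgeLen), edgeLen * scale * rate)
  counts <- vapply(seq_len(nTips), function(tip)
    sum(mut[vapply(edgeTips, function(s) tip %in% s, TRUE)]), 0)
  cladeCluster("sim-coalescent", counts,
               branches = data.frame(
                 nTips = vapply(edgeTips, length, 1L),
                 length = as.numeric(mut)))
}

#' Generate a clinal (or flat) haplogroup-frequency field over populations
#'
#' Population frequencies follow
#' value = clip(intercept + gLat * lat + gLon * lon + Normal(0, noiseSD))
#' on a regular latitude/longitude grid of population locations.
#'
#' @param lat,lon numeric vectors of grid coordinates (a full grid is formed).
#' @param intercept baseline frequency.
#' @param gLat,gLon gradient per degree of latitude / longitude.
#' @param noiseSD standard deviation of the Gaussian noise.
#' @param seed optional integer seed.
#' @return data.frame of geo-referenced frequencies with columns
#'   \code{population}, \code{lat}, \code{lon}, \code{value} in [0, 1].
#' @export
generateClinalPopulations <- function(lat = seq(10, 35, by = 5),
                                      lon = seq(-10, 30, by = 8),
                                      intercept = 0.5, gLat = 0, gLon = 0,
                                      noiseSD = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(lat = lat, lon = lon)
  raw <- intercept + gLat * g$lat + gLon * g$lon +
    stats::rnorm(nrow(g), 0, noiseSD)
  data.frame(population = paste0("p", seq_len(nrow(g))),
             lat = g$lat, lon = g$lon,
             value = pmin(1, pmax(0, raw)), stringsAsFactors = FALSE)
}

#' Draw a synthetic haplotype from a motif-tree node
#'
#' The haplotype carries the node's full cumulative motif plus
#' \code{nExtraMutations} random transitions at non-motif HVRI positions in
#' the window (private mutations).
#'
#' @param tree a \code{\linkS4class{MotifTree}}.
#' @param node node name.
#' @param nExtraMutations number of extra private transitions.
#' @param window length-2 window for the extra sites.
#' @param seed optional integer seed.
#' @param sample_id label for the output haplotype.
#' @return a \code{\linkS4class{HaplotypeSet}} of length 1.
#' @export
sampleFromMotif <- function(tree, node, nExtraMutations = 0L,
                            window = c(16024L, 16360L), seed = NULL,
                            sample_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  m <- nodeMotif(tree, node)
  if (nrow(m)) m$region <- .siteRegion(m$position)
  free <- setdiff(seq.int(window[1L], window[2L]), m$position)
  extra <- if (nExtraMutations > 0L)
    data.frame(region = "HVRI", position = sample(free, nExtraMutations),
               insertIndex = 0L, kind = "substitution", alleles = "",
               stringsAsFactors = FALSE)
  else NULL
  v <- rbind(if (nrow(m)) m[, c("region", "position", "insertIndex", "kind",
                                "alleles")],
             extra)
  if (is.null(v))
    v <- data.frame(region = character(), position = integer(),
                    insertIndex = integer(), kind = character(),
                    alleles = character(), stringsAsFactors = FALSE)
  v$sample_id <- rep(sample_id, nrow(v))
  new("HaplotypeSet", sampleID = sample_id, population = "synthetic",
      haplogroup = NA_character_, codingTyped = TRUE,
      variants = v[, c("sample_id", "region", "position", "insertIndex",
                       "kind", "alleles")])
}
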