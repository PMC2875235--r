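# Two-level AMOVA sums of squares from a squared-distance matrix (pairwise
# difference counts are squared Euclidean distances over sites, the classic
# convention for Phi-statistics). Returns variance components.
.amovaComponents <- function(d2, popIndex) {
  N <- nrow(d2)
  pops <- split(seq_len(N), popIndex)
  P <- length(pops)
  ssTotal <- sum(d2[upper.tri(d2)]) / N
  ssWithin <- sum(vapply(pops, function(idx) {
    if (length(idx) < 2L) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 0))
  ssAmong <- ssTotal - ssWithin
  dfAmong <- P - 1L
  dfWithin <- N - P
  msAmong <- ssAmong / dfAmong
  msWithin <- ssWithin / dfWithin
  sizes <- lengths(pops)
  nc <- (N - sum(sizes^2) / N) / (P - 1L)
  sigmaW <- msWithin
  sigmaA <- (msAmong - msWithin) / nc
  list(sigmaA = sigmaA, sigmaW = sigmaW,
       ssAmong = ssAmong, ssWithin = ssWithin,
       dfAmong = dfAmong, dfWithin = dfWithin)
}

#' Pairwise Phi-ST between two populations
#'
#' Excoffier-style Phi-ST from the two-level AMOVA on the pair, with
#' pairwise difference counts used as squared distances:
#' \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}.
#'
#' @param popA,popB \code{\linkS4class{HaplotypeSet}} objects (>= 2 samples
#'   each).
#' @inheritParams distanceMatrix
#' @return numeric Phi-ST (slightly negative values are possible and are
#'   reported as computed; exactly 0 with a warning when both populations are
#'   monomorphic and identical).
#' @export
pairwisePhiST <- function(popA, popB, policy = defaultPolicy(),
                          region = "HVRI") {
  stopifnot(length(popA) >= 2L, length(popB) >= 2L)
  ids <- make.unique(c(paste0("A.", sampleIDs(popA)),
                       paste0("B.", sampleIDs(popB))))
  combined <- c(.renameSamples(popA, ids[seq_along(sampleIDs(popA))]),
                .renameSamples(popB, ids[-seq_along(sampleIDs(popA))]))
  d2 <- distanceMatrix(combined, policy, region)
  if (all(d2 == 0)) {
    warning("all sequences identical in both populations; Phi-ST set to 0")
    return(0)
  }
  cp <- .amovaComponents(d2, rep(c("A", "B"),
                                 c(length(popA), length(popB))))
  cp$sigmaA / (cp$sigmaA + cp$sigmaW)
}

.renameSamples <- function(x, ids) {
  v <- x@variants
  v$sample_id <- ids[match(v$sample_id, x@sampleID)]
  new("HaplotypeSet", sampleID = ids, population = x@population,
      haplogroup = x@haplogroup, codingTyped = x@codingTyped, variants = v)
}

#' Two-level AMOVA over several populations
#'
#' Distance-based analysis of molecular variance: among-population and
#' within-population variance components and the among-population percentage
#' of total variation. Populations of size 1 are excluded with a warning.
#' Negative among-population components are reported as computed and flagged,
#' but truncated to zero in \code{percentAmong}.
#'
#' @param pops named list of \code{\linkS4class{HaplotypeSet}} objects.
#' @inheritParams distanceMatrix
#' @return list with \code{sigmaAmong}, \code{sigmaWithin},
#'   \code{percentAmong}, \code{percentWithin}, \code{negativeComponent}
#'   flag, and the degrees of freedom.
#' @export
amova <- function(pops, policy = defaultPolicy(), region = "HVRI") {
  stopifnot(length(pops) >= 2L)
  if (is.null(names(pops))) names(pops) <- paste0("pop", seq_along(pops))
  small <- vapply(pops, length, 1L) < 2L
  if (any(small)) {
    warning("excluding populations of size 1: ",
            paste(names(pops)[small], collapse = ", "))
    pops <- pops[!small]
    if (length(pops) < 2L) stop("fewer than 2 usable populations")
  }
  ids <- unlist(lapply(names(pops), function(nm)
    paste0(nm, ".", sampleIDs(pops[[nm]]))))
  combined <- do.call(c, lapply(seq_along(pops), function(i) {
    off <- sum(vapply(pops[seq_len(i - 1L)], length, 1L))
    .renameSamples(pops[[i]], ids[off + seq_len(length(pops[[i]]))])
  }))
  d2 <- distanceMatrix(combined, policy, region)
  popIndex <- rep(names(pops), vapply(pops, length, 1L))
  cp <- .amovaComponents(d2, popIndex)
  neg <- cp$sigmaA < 0
  sa <- max(cp$sigmaA, 0)
  list(sigmaAmong = cp$sigmaA, sigmaWithin = cp$sigmaW,
       percentAmong = 100 * sa / (sa + cp$sigmaW),
       percentWithin = 100 * cp$sigmaW / (sa + cp$sigmaW),
       negativeComponent = neg,
       dfAmong = cp$dfAmong, dfWithin = cp$dfWithin)
}

#' Permutation test for pairwise Phi-ST
#'
#' Permutes individuals between the two populations and reports the fraction
#' of permutations with Phi-ST at least as large as observed, with the
#' binomial standard error sqrt(p(1-p)/reps).
#'
#' @inheritParams pairwisePhiST
#' @param reps number of permutations (>= 100).
#' @param seed optional integer seed.
#' @return list with \code{phiST}, \code{p}, \code{SE}, \code{reps} and a
#'   \code{formatted} string in the conventional "p value = 0.000 +- 0.000"
#'   style.
#' @export
phistPermutationTest <- function(popA, popB, policy = defaultPolicy(),
                                 region = "HVRI", reps = 1000L, seed = NULL) {
  stopifnot(reps >= 100L)
  if (!is.null(seed)) set.seed(seed)
  nA <- length(popA)
  ids <- make.unique(c(paste0("A.", sampleIDs(popA)),
                       paste0("B.", sampleIDs(popB))))
  combined <- c(.renameSamples(popA, ids[seq_len(nA)]),
                .renameSamples(popB, ids[-seq_len(nA)]))
  d2 <- distanceMatrix(combined, policy, region)
  N <- nrow(d2)
  phiFromIndex <- function(idx) {
    cp <- .amovaComponents(d2, idx)
    cp$sigmaA / (cp$sigmaA + cp$sigmaW)
  }
  obsIndex <- rep(c("A", "B"), c(nA, N - nA))
  obs <- if (all(d2 == 0)) 0 else phiFromIndex(obsIndex)
  perm <- vapply(seq_len(reps), function(r)
    phiFromIndex(sample(obsIndex)), 0)
  p <- mean(perm >= obs - 1e-12)
  se <- sqrt(p * (1 - p) / reps)
  list(phiST = obs, p = p, SE = se, reps = reps,
       formatted = sprintf("p value = %.3f +- %.3f", p, se))
}

#' Bonferroni significance flags
#'
#' Flags p-values significant after Bonferroni correction for m comparisons:
#' p < alpha / m (equivalently, p.adjust(p, "bonferroni") < alpha).
#'
#' @param pvals numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @return logical vector.
#' @export
bonferroniFlags <- function(pvals, alpha = 0.05) {
  stats::p.adjust(pvals, method = "bonferroni") < alpha
}
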