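# md5 of the packaged El Jadida fixture; guards against silent corruption.
.eljadidaMD5 <- "88559aba7f8cb4753906ca9798bd6651"

#' Construct a distance policy
#'
#' The package default is the policy under which the packaged El Jadida survey
#' reproduces its published summary statistics: HVRI window 16024--16360,
#' insertions/deletions excluded from difference counting, heteroplasmic calls
#' counted as carrying their stated (non-reference) state.
#'
#' @param rangeStart,rangeEnd inclusive rCRS window bounds.
#' @param countIndels logical; count indel keys as differences.
#' @param countAmbiguous logical; count heteroplasmic calls (FALSE drops them).
#' @param excludedPositions integer positions removed before any counting
#'   (e.g. 16519 for clade dating).
#' @return a \code{\linkS4class{DistancePolicy}}.
#' @export
distancePolicy <- function(rangeStart = 16024L, rangeEnd = 16360L,
                           countIndels = FALSE, countAmbiguous = TRUE,
                           excludedPositions = integer()) {
  new("DistancePolicy", rangeStart = as.integer(rangeStart),
      rangeEnd = as.integer(rangeEnd), countIndels = countIndels,
      countAmbiguous = countAmbiguous,
      excludedPositions = as.integer(excludedPositions))
}

#' @rdname distancePolicy
#' @export
defaultPolicy <- function() distancePolicy()

# Per-sample windowed profiles under a policy: named character vectors mapping
# variant key ("position.insertIndex.kind") to rendered state.
.profiles <- function(x, policy, region = "HVRI") {
  v <- x@variants
  v <- v[v$region %in% region &
         v$position >= policy@rangeStart & v$position <= policy@rangeEnd &
         !(v$position %in% policy@excludedPositions), , drop = FALSE]
  if (!policy@countIndels) v <- v[v$kind == "substitution", , drop = FALSE]
  if (!policy@countAmbiguous) v <- v[!grepl("/", v$alleles), , drop = FALSE]
  key <- paste(v$position, v$insertIndex, substr(v$kind, 1L, 1L), sep = ".")
  state <- paste(v$kind, v$alleles, sep = ":")
  out <- lapply(x@sampleID, function(id) {
    sel <- v$sample_id == id
    structure(state[sel], names = key[sel])
  })
  names(out) <- x@sampleID
  out
}

.pairDiff <- function(a, b) {
  shared <- intersect(names(a), names(b))
  length(a) + length(b) - 2L * length(shared) +
    sum(a[shared] != b[shared])
}

#' Pairwise difference between two haplotypes under a policy
#'
#' Counts the variant keys (position, insertion index, kind) inside the policy
#' window at which the two haplotypes differ; a key carried by both counts
#' only when the rendered states differ (e.g. a transition vs a transversion,
#' or two heteroplasmic calls with different allele sets). The count is
#' symmetric and zero iff the windowed profiles are identical.
#'
#' @param a,b \code{\linkS4class{HaplotypeSet}} objects of length 1 (or a
#'   common set subset by sample ID).
#' @param policy a \code{\linkS4class{DistancePolicy}}.
#' @param region region label(s) to compare within (default HVRI).
#' @return non-negative integer.
#' @export
haplotypeDistance <- function(a, b, policy = defaultPolicy(),
                              region = "HVRI") {
  stopifnot(length(a) == 1L, length(b) == 1L)
  pa <- .profiles(a, policy, region)[[1L]]
  pb <- .profiles(b, policy, region)[[1L]]
  .pairDiff(pa, pb)
}

#' Matrix of pairwise differences for a haplotype set
#'
#' @param x a \code{\linkS4class{HaplotypeSet}}.
#' @inheritParams haplotypeDistance
#' @return symmetric integer matrix with sample IDs as dimnames.
#' @export
distanceMatrix <- function(x, policy = defaultPolicy(), region = "HVRI") {
  pr <- .profiles(x, policy, region)
  n <- length(pr)
  d <- matrix(0L, n, n, dimnames = list(names(pr), names(pr)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- .pairDiff(pr[[i]], pr[[j]])
    }
  }
  d
}

#' Distinct haplotypes and segregating sites under a policy
#'
#' \code{distinctHaplotypes} counts unique windowed profiles;
#' \code{segregatingSites} counts variant keys segregating in the window.
#'
#' @inheritParams distanceMatrix
#' @return integer scalar.
#' @export
distinctHaplotypes <- function(x, policy = defaultPolicy(), region = "HVRI") {
  pr <- .profiles(x, policy, region)
  sig <- vapply(pr, function(p) {
    o <- order(names(p))
    paste(names(p)[o], p[o], sep = "=", collapse = ";")
  }, "")
  length(unique(sig))
}

#' @rdname distinctHaplotypes
#' @export
segregatingSites <- function(x, policy = defaultPolicy(), region = "HVRI") {
  pr <- .profiles(x, policy, region)
  length(unique(unlist(lapply(pr, names), use.names = FALSE)))
}
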