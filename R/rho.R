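#' Clock calibration constructor
#'
#' @param yearsPerMutation years per mutation; the default 3624 is the
#'   whole-molecule rate used for rho-based founder dating of mtDNA clades.
#' @param label free-text description.
#' @return a \code{\linkS4class{ClockCalibration}}.
#' @export
clockCalibration <- function(yearsPerMutation = 3624,
                             label = "1 mutation per 3624 years") {
  new("ClockCalibration", yearsPerMutation = yearsPerMutation, label = label)
}

#' The rho statistic
#'
#' The average number of mutations from the clade's ancestral haplotype to
#' every sampled sequence:
#' \eqn{\rho = \sum_t c_t m_t / \sum_t m_t} over tips with mutation count
#' \eqn{c_t} and multiplicity \eqn{m_t}. With
#' \code{sharedTipsOnce = TRUE} a tip haplotype shared by several samples
#' contributes its terminal mutations once (the multiplicities still count
#' toward N), matching the convention of counting each tip node as one event
#' when shared by a few samples.
#'
#' @param cluster a \code{\linkS4class{CladeCluster}}.
#' @param sharedTipsOnce logical; see above (default FALSE: plain weighted
#'   mean).
#' @return numeric rho.
#' @examples
#' rhoStatistic(cladeCluster("x", c(1, 1, 2, 0)))  # 1
#' @export
rhoStatistic <- function(cluster, sharedTipsOnce = FALSE) {
  tp <- cluster@tips
  N <- sum(tp$multiplicity)
  if (N < 1) stop("empty cluster")
  if (sharedTipsOnce) sum(tp$count) / N
  else sum(tp$count * tp$multiplicity) / N
}

#' Standard error of rho
#'
#' Branch-weighted Poisson variance (Saillard-type):
#' \eqn{\sigma_\rho = \sqrt{\sum_b (n_b/N)^2 l_b}} over branches with
#' \eqn{n_b} descendant tips and length \eqn{l_b} mutations. When no branch
#' table is available and \code{star = TRUE}, the star-phylogeny form
#' \eqn{\sqrt{\sum_t c_t}/N} is used.
#'
#' @param cluster a \code{\linkS4class{CladeCluster}}.
#' @param star allow the star assumption when branches are missing.
#' @return numeric standard error.
#' @export
rhoSigma <- function(cluster, star = TRUE) {
  tp <- cluster@tips
  N <- sum(tp$multiplicity)
  br <- cluster@branches
  if (nrow(br)) {
    sqrt(sum((br$nTips / N)^2 * br$length))
  } else if (star) {
    sqrt(sum(tp$count * tp$multiplicity)) / N
  } else {
    stop("no branch table and the star assumption is disabled")
  }
}

#' Convert rho and sigma to an age in years
#'
#' years = rho * yearsPerMutation; the hypervariable site 16519 must have
#' been excluded upstream (via the DistancePolicy) when counting mutations.
#' An optional user-supplied transform hook (e.g. a purifying-selection
#' correction) is applied to both the point estimate and the SD.
#'
#' @param rho rho statistic.
#' @param sigma its standard error (same mutation units).
#' @param cal a \code{\linkS4class{ClockCalibration}}.
#' @param transform optional function years -> corrected years.
#' @return named numeric vector \code{c(years, sd)}.
#' @export
rhoAge <- function(rho, sigma, cal = clockCalibration(), transform = identity) {
  c(years = transform(rho * cal@yearsPerMutation),
    sd = transform(sigma * cal@yearsPerMutation))
}

#' Read clade clusters from a TSV of tips
#'
#' Columns: \code{clade}, \code{id}, \code{count}, \code{multiplicity}.
#'
#' @param path file path.
#' @return named list of \code{\linkS4class{CladeCluster}} objects.
#' @export
readCladeTable <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("clade", "id", "count") %in% names(tab)))
    stop("clade table needs columns clade, id, count")
  if (is.null(tab$multiplicity)) tab$multiplicity <- 1L
  lapply(split(tab, tab$clade), function(cl)
    cladeCluster(cl$clade[1L], cl$count, cl$multiplicity, ids = cl$id))
}
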