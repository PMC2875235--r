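#' @import methods
NULL

#' Distance policy for rCRS-relative haplotype comparison
#'
#' A \code{DistancePolicy} bundles the conventions under which two
#' control-region haplotypes are compared: the analysis window on the rCRS,
#' whether insertions/deletions count as differences, whether heteroplasmic
#' ("X/Y") calls count, and positions excluded outright (e.g. the hypervariable
#' site 16519 for clade dating).
#'
#' Two haplotypes differ at a variant key (position, insertion index, kind)
#' inside the window if exactly one of them carries a variant there, or if both
#' do but the rendered states differ (a plain transition, a transversion to a
#' named base, and distinct heteroplasmic allele sets are distinct states).
#'
#' @slot rangeStart,rangeEnd integer rCRS positions bounding the window
#'   (inclusive).
#' @slot countIndels logical; count insertion/deletion keys as differences.
#' @slot countAmbiguous logical; if \code{FALSE}, heteroplasmic calls are
#'   treated as reference (dropped) before counting.
#' @slot excludedPositions integer vector of positions removed before any
#'   counting.
#' @exportClass DistancePolicy
setClass("DistancePolicy",
  representation(rangeStart = "integer", rangeEnd = "integer",
                 countIndels = "logical", countAmbiguous = "logical",
                 excludedPositions = "integer"),
  prototype(rangeStart = 16024L, rangeEnd = 16360L, countIndels = FALSE,
            countAmbiguous = TRUE, excludedPositions = integer()))

setValidity("DistancePolicy", function(object) {
  msg <- character()
  if (length(object@rangeStart) != 1L || length(object@rangeEnd) != 1L)
    msg <- c(msg, "rangeStart and rangeEnd must be single positions")
  else if (object@rangeStart >= object@rangeEnd)
    msg <- c(msg, "rangeStart must be < rangeEnd")
  if (any(c(object@rangeStart, object@rangeEnd) < 1L) ||
      any(c(object@rangeStart, object@rangeEnd) > 16569L))
    msg <- c(msg, "window must lie within rCRS positions 1..16569")
  if (length(msg)) msg else TRUE
})

#' Set of rCRS-relative haplotypes
#'
#' The central container: one row of sample-level metadata per individual and a
#' long-format table of parsed variants. Variants are keyed by
#' (position, insertIndex, kind) within a region (HVRI, HVRII or CODING);
#' HVRI positions are stored restored to absolute rCRS coordinates
#' (16024--16569).
#'
#' @slot sampleID character vector of unique sample labels.
#' @slot population character vector, one population label per sample.
#' @slot haplogroup character vector of haplogroup labels (NA when unknown).
#' @slot codingTyped logical; TRUE when coding-region segments were sequenced
#'   for the sample, so an absent coding variant is evidence of absence.
#' @slot variants data.frame with columns \code{sample_id}, \code{region},
#'   \code{position}, \code{insertIndex}, \code{kind}, \code{alleles}.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(sampleID = "character", population = "character",
                 haplogroup = "character", codingTyped = "logical",
                 variants = "data.frame"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  n <- length(object@sampleID)
  if (anyDuplicated(object@sampleID))
    msg <- c(msg, "sample IDs must be unique")
  if (length(object@population) != n || length(object@haplogroup) != n ||
      length(object@codingTyped) != n)
    msg <- c(msg, "per-sample slots must have one entry per sample")
  v <- object@variants
  need <- c("sample_id", "region", "position", "insertIndex", "kind", "alleles")
  if (!all(need %in% names(v))) {
    msg <- c(msg, paste("variants table must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(v)) {
    if (!all(v$sample_id %in% object@sampleID))
      msg <- c(msg, "variants refer to unknown sample IDs")
    if (!all(v$region %in% c("HVRI", "HVRII", "CODING")))
      msg <- c(msg, "region must be HVRI, HVRII or CODING")
    if (anyDuplicated(v[, c("sample_id", "region", "position",
                            "insertIndex", "kind")]))
      msg <- c(msg, "duplicate variant key within a sample/region")
    hv1 <- v$position[v$region == "HVRI"]
    if (length(hv1) && (any(hv1 < 16001L) || any(hv1 > 16569L)))
      msg <- c(msg, "HVRI variants must lie in 16001..16569 after offset restoration")
    if (any(v$position < 1L | v$position > 16569L))
      msg <- c(msg, "positions must lie in 1..16569")
    if (any((v$insertIndex > 0L) != (v$kind == "insertion")))
      msg <- c(msg, "insertIndex > 0 exactly for insertions")
  }
  if (length(msg)) msg else TRUE
})

#' Haplogroup motif tree
#'
#' A rooted tree of haplogroup labels, each node carrying the set of
#' rCRS-relative variants expected on the path from the root (its cumulative
#' motif). Motif positions are absolute rCRS coordinates.
#'
#' @slot nodes data.frame with columns \code{name}, \code{parent}
#'   (NA for the root) and \code{depth}.
#' @slot motifs named list; for each node, a data.frame of its own motif
#'   variants (columns as in a HaplotypeSet variants table, minus sample_id).
#' @exportClass MotifTree
setClass("MotifTree",
  representation(nodes = "data.frame", motifs = "list"))

setValidity("MotifTree", function(object) {
  msg <- character()
  nd <- object@nodes
  if (!all(c("name", "parent", "depth") %in% names(nd)))
    return("nodes must have columns name, parent, depth")
  if (anyDuplicated(nd$name)) msg <- c(msg, "node names must be unique")
  root <- is.na(nd$parent)
  if (sum(root) != 1L) msg <- c(msg, "tree must have exactly one root")
  if (!all(nd$parent[!root] %in% nd$name))
    msg <- c(msg, "every non-root parent must name an existing node")
  if (!setequal(names(object@motifs), nd$name))
    msg <- c(msg, "motifs must be a named list covering every node")
  if (length(msg)) msg else TRUE
})

#' Mutation-annotated clade cluster for rho dating
#'
#' Tips carry the number of mutations separating them from the cluster's
#' ancestral haplotype; an optional branch table (descendant-tip count and
#' length in mutations per branch) supports the Saillard-type standard error
#' on non-star genealogies.
#'
#' @slot name character label for the clade.
#' @slot tips data.frame with columns \code{id}, \code{count},
#'   \code{multiplicity}.
#' @slot branches data.frame with columns \code{nTips}, \code{length}, or a
#'   zero-row data.frame when only the star assumption is available.
#' @exportClass CladeCluster
setClass("CladeCluster",
  representation(name = "character", tips = "data.frame",
                 branches = "data.frame"))

setValidity("CladeCluster", function(object) {
  msg <- character()
  tp <- object@tips
  if (!all(c("id", "count", "multiplicity") %in% names(tp)))
    return("tips must have columns id, count, multiplicity")
  if (nrow(tp) < 1L) msg <- c(msg, "a clade needs at least one tip")
  if (any(tp$count < 0) || any(tp$multiplicity < 1))
    msg <- c(msg, "mutation counts must be >= 0 and multiplicities >= 1")
  br <- object@branches
  if (nrow(br)) {
    if (!all(c("nTips", "length") %in% names(br)))
      msg <- c(msg, "branches must have columns nTips, length")
    else {
      tipTotal <- sum(tp$count * tp$multiplicity)
      brTotal <- sum(br$nTips * br$length)
      if (abs(tipTotal - brTotal) > 1e-8)
        msg <- c(msg, "branch bookkeeping must satisfy sum(nTips*length) == sum(count*multiplicity)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Molecular clock calibration
#'
#' @slot yearsPerMutation positive number of years per mutation (default 3624,
#'   the whole-molecule control-region-calibrated rate used for rho dating).
#' @slot label character description of the calibration.
#' @exportClass ClockCalibration
setClass("ClockCalibration",
  representation(yearsPerMutation = "numeric", label = "character"),
  prototype(yearsPerMutation = 3624, label = "1 mutation per 3624 years"))

setValidity("ClockCalibration", function(object) {
  if (length(object@yearsPerMutation) != 1L || object@yearsPerMutation <= 0)
    "yearsPerMutation must be a single positive number" else TRUE
})

#' Inverse-distance-weighted frequency surface
#'
#' @slot grid data.frame with columns \code{lon}, \code{lat}, \code{value}.
#' @slot power IDW power used.
#' @slot points the input points (data.frame population, lat, lon, value).
#' @exportClass FrequencySurface
setClass("FrequencySurface",
  representation(grid = "data.frame", power = "numeric", points = "data.frame"))

#' Moran's I distance-class correlogram
#'
#' @slot classes data.frame with one row per distance class: \code{class},
#'   \code{lower}, \code{upper}, \code{meanDist}, \code{nPairs}, \code{I},
#'   \code{p}.
#' @slot nPoints number of spatial points.
#' @slot reps permutation replicates used for the per-class p-values.
#' @exportClass Correlogram
setClass("Correlogram",
  representation(classes = "data.frame", nPoints = "integer",
                 reps = "integer"))

setMethod("show", "DistancePolicy", function(object) {
  cat("DistancePolicy: window", object@rangeStart, "-", object@rangeEnd,
      "| indels", if (object@countIndels) "counted" else "excluded",
      "| heteroplasmies", if (object@countAmbiguous) "counted" else "excluded",
      "\n")
  if (length(object@excludedPositions))
    cat("  excluded positions:",
        paste(object@excludedPositions, collapse = ", "), "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet with", length(object@sampleID), "haplotypes,",
      nrow(object@variants), "variants\n")
  pops <- table(object@population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  hg <- object@haplogroup
  cat("  haplogroup labels:", sum(!is.na(hg)), "of", length(hg), "assigned\n")
})

setMethod("show", "MotifTree", function(object) {
  cat("MotifTree with", nrow(object@nodes), "nodes, root",
      sQuote(object@nodes$name[is.na(object@nodes$parent)]), "\n")
})

setMethod("show", "CladeCluster", function(object) {
  cat("CladeCluster", sQuote(object@name), "with",
      sum(object@tips$multiplicity), "samples over", nrow(object@tips),
      "tips;", if (nrow(object@branches)) "branch table available"
      else "star assumption", "\n")
})

setMethod("show", "Correlogram", function(object) {
  cat("Correlogram over", nrow(object@classes), "distance classes (",
      object@nPoints, "points,", object@reps, "permutations )\n")
  print(object@classes, digits = 3, row.names = FALSE)
})

setMethod("show", "FrequencySurface", function(object) {
  cat("FrequencySurface:", nrow(object@grid), "grid cells, IDW power",
      object@power, "from", nrow(object@points), "points\n")
})
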