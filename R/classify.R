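#' Read a haplogroup motif tree from TSV
#'
#' The file has columns \code{name}, \code{parent} (empty for the root) and
#' \code{motif}: whitespace-separated variant tokens in absolute rCRS
#' coordinates (HVRI sites are not offset). A node's effective motif is the
#' union of its own tokens and those of all its ancestors.
#'
#' @param path TSV file path.
#' @return a \code{\linkS4class{MotifTree}}.
#' @export
readMotifTree <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  names(tab) <- tolower(names(tab))
  if (!nrow(tab)) stop("empty motif tree")
  if (!all(c("name", "parent") %in% names(tab)))
    stop("motif tree needs columns name, parent")
  if (is.null(tab$motif)) tab$motif <- ""
  parent <- ifelse(nzchar(trimws(tab$parent)), tab$parent, NA_character_)
  motifs <- lapply(seq_len(nrow(tab)), function(i) {
    txt <- trimws(tab$motif[i])
    if (!nzchar(txt))
      return(data.frame(region = character(), position = integer(),
                        insertIndex = integer(), kind = character(),
                        alleles = character(), stringsAsFactors = FALSE))
    do.call(rbind, lapply(strsplit(txt, "[[:space:]]+")[[1L]],
                          parseVariantToken, region = NA_character_))
  })
  names(motifs) <- tab$name
  depth <- integer(nrow(tab)); names(depth) <- tab$name
  for (i in seq_len(nrow(tab))) {
    d <- 0L; p <- parent[i]
    while (!is.na(p)) {
      d <- d + 1L
      if (d > nrow(tab)) stop("cycle in motif tree at node ", tab$name[i])
      p <- parent[match(p, tab$name)]
    }
    depth[i] <- d
  }
  new("MotifTree",
      nodes = data.frame(name = tab$name, parent = parent, depth = depth,
                         stringsAsFactors = FALSE),
      motifs = motifs)
}

#' Load the packaged motif tree for the El Jadida haplogroups
#' @return a \code{\linkS4class{MotifTree}}.
#' @export
elJadidaMotifTree <- function() {
  readMotifTree(system.file("extdata", "motif_tree.tsv",
                            package = "mtPopGen", mustWork = TRUE))
}

#' @rdname treeNodes
#' @export
nodeAncestors <- function(tree, name) {
  nd <- tree@nodes
  out <- character(); p <- nd$parent[match(name, nd$name)]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- nd$parent[match(p, nd$name)]
  }
  out
}

#' Motif tree accessors
#'
#' \code{treeNodes} returns the node table; \code{nodeMotif} the cumulative
#' motif of a node (own tokens plus all ancestors'); \code{nodeAncestors} the
#' ancestor names from parent to root; \code{macroPool} maps haplogroup labels
#' to the sub-Saharan L pool vs the West Eurasian pool; \code{lBranch} returns
#' the top-level L branch (L0..L6) of a label, or NA.
#'
#' @param tree a \code{\linkS4class{MotifTree}}.
#' @param name a node name.
#' @export
treeNodes <- function(tree) tree@nodes

#' @rdname treeNodes
#' @export
nodeMotif <- function(tree, name) {
  stopifnot(name %in% tree@nodes$name)
  chain <- c(name, nodeAncestors(tree, name))
  m <- do.call(rbind, tree@motifs[chain])
  unique(m)
}

#' @rdname treeNodes
#' @param labels character vector of haplogroup labels.
#' @export
macroPool <- function(labels) {
  ifelse(grepl("^L[0-6]", labels), "sub-Saharan L", "West Eurasian")
}

#' @rdname treeNodes
#' @export
lBranch <- function(labels) {
  out <- rep(NA_character_, length(labels))
  hit <- grepl("^L[0-6]", labels)
  out[hit] <- substr(labels[hit], 1L, 2L)
  out
}

# Region of an absolute rCRS position: the control region spans 16024..16569
# (HVRI) and 1..576 (HVRII for our purposes); everything else is coding.
.siteRegion <- function(pos) {
  ifelse(pos >= 16024L, "HVRI", ifelse(pos <= 576L, "HVRII", "CODING"))
}

#' Assign haplotypes to haplogroups by motif best match
#'
#' Each node is scored as (matched motif sites) - lambda * (motif sites absent
#' from regions the sample was typed for); motif sites are matched by variant
#' key (position, insertion index, kind) regardless of the called allele, so a
#' heteroplasmic call satisfies a motif site. Coding-region motif sites are
#' only penalised when the sample's coding segments were sequenced
#' (\code{codingTyped}): an untyped site is unobserved, not absent. The
#' best-scoring node wins; among equal scores on a single root path the
#' deepest node wins; equal scores across different paths are reported in the
#' \code{ties} column and never silently broken.
#'
#' @param x a \code{\linkS4class{HaplotypeSet}}.
#' @param tree a \code{\linkS4class{MotifTree}}.
#' @param lambda penalty per missing motif site (default 0.6).
#' @return data.frame with columns \code{sample_id}, \code{haplogroup}
#'   (best node), \code{score}, \code{matched}, \code{missing}, \code{ties}
#'   (comma-separated equal-scoring off-path nodes, \code{""} if none), and
#'   \code{macro}.
#' @examples
#' ej <- loadElJadida()
#' head(classifyHaplotypes(ej, elJadidaMotifTree()))
#' @export
classifyHaplotypes <- function(x, tree, lambda = 0.6) {
  if (!nrow(tree@nodes)) stop("empty motif tree")
  nd <- tree@nodes
  cums <- lapply(nd$name, function(nm) {
    m <- nodeMotif(tree, nm)
    if (!nrow(m)) return(character())
    unique(paste(m$position, m$insertIndex, substr(m$kind, 1L, 1L),
                 sep = "."))
  })
  names(cums) <- nd$name
  regions <- lapply(cums, function(k) {
    if (!length(k)) return(character())
    .siteRegion(as.integer(sub("\\..*", "", k)))
  })
  v <- x@variants
  vkey <- paste(v$position, v$insertIndex, substr(v$kind, 1L, 1L), sep = ".")
  rows <- lapply(seq_along(x@sampleID), function(i) {
    id <- x@sampleID[i]
    obs <- vkey[v$sample_id == id]
    score <- matched <- missing <- numeric(nrow(nd))
    for (k in seq_len(nrow(nd))) {
      mk <- cums[[k]]
      hit <- mk %in% obs
      matched[k] <- sum(hit)
      observable <- regions[[k]] != "CODING" | x@codingTyped[i]
      missing[k] <- sum(!hit & observable)
      score[k] <- matched[k] - lambda * missing[k]
    }
    top <- which(score > max(score) - 1e-9)
    best <- top[which.max(nd$depth[top])]
    anc <- c(nd$name[best], nodeAncestors(tree, nd$name[best]))
    ties <- setdiff(nd$name[top], anc)
    data.frame(sample_id = id, haplogroup = nd$name[best],
               score = score[best], matched = matched[best],
               missing = missing[best],
               ties = paste(ties, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$macro <- macroPool(out$haplogroup)
  out
}

#' Tabulate haplogroup frequencies
#'
#' With \code{grouping = "total"}, counts and proportions of each assigned
#' haplogroup over all samples, plus the macro split between the sub-Saharan
#' L pool and the West Eurasian pool. With \code{grouping = "withinL"},
#' the shares of the top-level L branches (L1, L2, L3, ...) within the
#' sub-Saharan pool.
#'
#' @param assignments data.frame from \code{\link{classifyHaplotypes}} (any
#'   data.frame with a \code{haplogroup} column works).
#' @param grouping \code{"total"} or \code{"withinL"}.
#' @return data.frame with columns \code{label}, \code{count},
#'   \code{proportion} (proportions sum to 1 over the chosen denominator).
#' @export
tabulateHaplogroups <- function(assignments, grouping = c("total", "withinL")) {
  grouping <- match.arg(grouping)
  hg <- assignments$haplogroup
  if (anyNA(hg) || any(!nzchar(hg)))
    stop("assignments contain unknown labels for samples: ",
         paste(assignments$sample_id[is.na(hg) | !nzchar(hg)], collapse = ", "))
  if (grouping == "total") {
    tab <- table(hg)
    out <- data.frame(label = names(tab), count = as.integer(tab),
                      proportion = as.numeric(tab) / length(hg),
                      stringsAsFactors = FALSE)
  } else {
    inL <- macroPool(hg) == "sub-Saharan L"
    if (!any(inL)) stop("no sub-Saharan L samples in the assignments")
    br <- lBranch(hg[inL])
    tab <- table(br)
    out <- data.frame(label = names(tab), count = as.integer(tab),
                      proportion = as.numeric(tab) / sum(inL),
                      stringsAsFactors = FALSE)
  }
  stopifnot(abs(sum(out$proportion) - 1) < 1e-9)
  out[order(out$label), , drop = FALSE]
}
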