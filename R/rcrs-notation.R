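#' Parse a single rCRS-relative variant token
#'
#' Tokens follow the control-region survey dialect: a bare integer is a
#' transition at that position; integer+base a transversion to the stated base;
#' \code{"318A/C"} a heteroplasmic/ambiguous call; \code{"309.1"},
#' \code{"309.2"} insertions after the position (inserted base defaults to C);
#' \code{"193del"} / \code{"193d"} a deletion; \code{"196insT"} an insertion of
#' the stated base. For \code{region = "HVRI"} printed positions below 16000
#' are offsets that are restored by +16000.
#'
#' @param token character scalar, one variant token.
#' @param region one of \code{"HVRI"}, \code{"HVRII"}, \code{"CODING"}, or
#'   \code{NA} for tokens already in absolute coordinates (motif files).
#' @return one-row data.frame with columns \code{region}, \code{position},
#'   \code{insertIndex}, \code{kind}, \code{alleles}. \code{alleles} is
#'   \code{""} for a plain transition, the base(s) otherwise (ambiguous calls
#'   are stored with sorted alleles, e.g. \code{"A/C"}).
#' @examples
#' parseVariantToken("129", "HVRI")      # transition at 16129
#' parseVariantToken("309.2", "HVRII")   # second C insertion after 309
#' parseVariantToken("318A/C", "HVRI")   # heteroplasmic call at 16318
#' @export
parseVariantToken <- function(token, region = NA_character_) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- trimws(token)
  pos <- NA_integer_; idx <- 0L; kind <- NA_character_; al <- ""
  if (grepl("^[0-9]+$", tok)) {
    pos <- as.integer(tok); kind <- "substitution"
  } else if (grepl("^[0-9]+\\.[0-9]+$", tok)) {
    sp <- strsplit(tok, ".", fixed = TRUE)[[1L]]
    pos <- as.integer(sp[1L]); idx <- as.integer(sp[2L])
    kind <- "insertion"; al <- "C"
    if (idx < 1L) stop("malformed variant token: ", sQuote(token))
  } else if (grepl("^[0-9]+(del|d)$", tok)) {
    pos <- as.integer(sub("(del|d)$", "", tok)); kind <- "deletion"
  } else if (grepl("^[0-9]+ins[ACGT]+$", tok)) {
    pos <- as.integer(sub("ins[ACGT]+$", "", tok))
    al <- sub("^[0-9]+ins", "", tok)
    idx <- 1L; kind <- "insertion"
  } else if (grepl("^[0-9]+[ACGT]/[ACGT]$", tok)) {
    pos <- as.integer(sub("[ACGT]/[ACGT]$", "", tok))
    ab <- sort(strsplit(sub("^[0-9]+", "", tok), "/", fixed = TRUE)[[1L]])
    al <- paste(ab, collapse = "/"); kind <- "substitution"
  } else if (grepl("^[0-9]+[ACGT]$", tok)) {
    pos <- as.integer(sub("[ACGT]$", "", tok))
    al <- sub("^[0-9]+", "", tok); kind <- "substitution"
  } else {
    stop("malformed variant token: ", sQuote(token))
  }
  if (!is.na(region) && region == "HVRI" && pos < 16000L) pos <- pos + 16000L
  if (pos < 1L || pos > 16569L)
    stop("position out of rCRS range 1..16569 in token ", sQuote(token))
  data.frame(region = if (is.na(region)) NA_character_ else region,
             position = pos, insertIndex = idx, kind = kind,
             alleles = al, stringsAsFactors = FALSE)
}

#' Render a parsed variant back to its canonical token
#'
#' The canonical rendering round-trips through \code{\link{parseVariantToken}}:
#' HVRI positions are printed minus 16000, heteroplasmic alleles sorted,
#' deletions use the \code{"del"} suffix, C-tract insertions the
#' \code{".k"} suffix and other insertions the \code{"insX"} suffix.
#'
#' @param v one-row data.frame as returned by \code{parseVariantToken} (or a
#'   multi-row table, rendered element-wise).
#' @return character vector of canonical tokens.
#' @export
renderVariant <- function(v) {
  pos <- ifelse(!is.na(v$region) & v$region == "HVRI",
                v$position - 16000L, v$position)
  out <- character(nrow(v))
  sub <- v$kind == "substitution"
  out[sub] <- paste0(pos[sub], v$alleles[sub])
  del <- v$kind == "deletion"
  out[del] <- paste0(pos[del], "del")
  ins <- v$kind == "insertion"
  plainC <- ins & v$alleles == "C"
  out[plainC] <- paste0(pos[plainC], ".", v$insertIndex[plainC])
  other <- ins & v$alleles != "C"
  out[other] <- paste0(pos[other], "ins", v$alleles[other])
  out
}

.parseRegionField <- function(text, region, sample_id) {
  text <- trimws(text)
  if (is.na(text) || text == "" || text == "0")
    return(NULL)
  toks <- strsplit(text, "[[:space:]]+")[[1L]]
  out <- do.call(rbind, lapply(toks, parseVariantToken, region = region))
  key <- paste(out$position, out$insertIndex, out$kind)
  if (anyDuplicated(key))
    stop("duplicate variant key in ", region, " of sample ", sample_id, ": ",
         paste(toks[duplicated(key) | duplicated(key, fromLast = TRUE)],
               collapse = ", "))
  out$sample_id <- sample_id
  out
}

#' Parse one sample row of variant strings into a haplotype
#'
#' \code{"0"} (or an empty string) denotes identity to the rCRS in that
#' region.
#'
#' @param sample_id sample label.
#' @param hvri,hvrii,other whitespace-separated variant-token strings for
#'   HVRI, HVRII and the typed coding segments.
#' @param population population label.
#' @param haplogroup optional haplogroup label.
#' @param codingTyped logical; were coding segments sequenced for this sample?
#' @return a \code{\linkS4class{HaplotypeSet}} of length 1.
#' @export
parseHaplotypeRow <- function(sample_id, hvri, hvrii, other = "",
                              population = "pop", haplogroup = NA_character_,
                              codingTyped = nzchar(trimws(other))) {
  v <- rbind(.parseRegionField(hvri, "HVRI", sample_id),
             .parseRegionField(hvrii, "HVRII", sample_id),
             .parseRegionField(other, "CODING", sample_id))
  if (is.null(v))
    v <- data.frame(sample_id = character(), region = character(),
                    position = integer(), insertIndex = integer(),
                    kind = character(), alleles = character(),
                    stringsAsFactors = FALSE)
  new("HaplotypeSet", sampleID = sample_id, population = population,
      haplogroup = as.character(haplogroup), codingTyped = codingTyped,
      variants = v[, c("sample_id", "region", "position", "insertIndex",
                       "kind", "alleles")])
}

#' @describeIn HaplotypeSet number of haplotypes in the set
#' @param x a HaplotypeSet
#' @export
setMethod("length", "HaplotypeSet", function(x) length(x@sampleID))

#' @describeIn HaplotypeSet subset by index, logical mask or sample ID
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleID)
  ids <- x@sampleID[i]
  new("HaplotypeSet", sampleID = ids, population = x@population[i],
      haplogroup = x@haplogroup[i], codingTyped = x@codingTyped[i],
      variants = x@variants[x@variants$sample_id %in% ids, , drop = FALSE])
})

#' Accessors for HaplotypeSet metadata
#'
#' @param x a \code{\linkS4class{HaplotypeSet}}
#' @return character vectors (or the long variants data.frame for
#'   \code{variantTable}).
#' @export
sampleIDs <- function(x) x@sampleID

#' @rdname sampleIDs
#' @export
haplogroups <- function(x) structure(x@haplogroup, names = x@sampleID)

#' @rdname sampleIDs
#' @export
populations <- function(x) structure(x@population, names = x@sampleID)

#' @rdname sampleIDs
#' @export
variantTable <- function(x) x@variants

#' Combine HaplotypeSet objects
#' @param x,... HaplotypeSet objects to concatenate.
#' @export
setMethod("c", "HaplotypeSet", function(x, ...) {
  all <- c(list(x), list(...))
  new("HaplotypeSet",
      sampleID = unlist(lapply(all, function(h) h@sampleID)),
      population = unlist(lapply(all, function(h) h@population)),
      haplogroup = unlist(lapply(all, function(h) h@haplogroup)),
      codingTyped = unlist(lapply(all, function(h) h@codingTyped)),
      variants = do.call(rbind, lapply(all, function(h) h@variants)))
})

#' Read a population table of variant-string haplotypes
#'
#' The TSV format has columns \code{sample_id}, \code{population},
#' \code{HVRI}, \code{HVRII}, \code{OTHER}, and optionally \code{haplogroup}
#' and \code{coding_typed}; \code{#}-prefixed lines are comments. \code{"0"}
#' or an empty field means identity to the rCRS in that region.
#'
#' @param path file path.
#' @return a \code{\linkS4class{HaplotypeSet}}.
#' @export
readPopulationTable <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  names(tab) <- tolower(names(tab))
  need <- c("sample_id", "hvri", "hvrii")
  if (!all(need %in% names(tab)))
    stop("population table needs columns sample_id, HVRI, HVRII")
  if (is.null(tab$population)) tab$population <- "pop"
  if (is.null(tab$other)) tab$other <- ""
  if (is.null(tab$haplogroup)) tab$haplogroup <- NA_character_
  typed <- if (is.null(tab$coding_typed)) nzchar(trimws(tab$other))
           else tab$coding_typed %in% c("1", "TRUE", "true")
  hs <- lapply(seq_len(nrow(tab)), function(i)
    parseHaplotypeRow(tab$sample_id[i], tab$hvri[i], tab$hvrii[i],
                      tab$other[i], tab$population[i], tab$haplogroup[i],
                      typed[i]))
  do.call(c, hs)
}

#' Write a HaplotypeSet as a population TSV
#'
#' @param x a \code{\linkS4class{HaplotypeSet}}.
#' @param path output file path.
#' @param header optional character vector of \code{#} comment lines.
#' @export
writePopulationTable <- function(x, path, header = NULL) {
  regionString <- function(id, region) {
    v <- x@variants[x@variants$sample_id == id &
                    x@variants$region == region, , drop = FALSE]
    if (!nrow(v)) return(if (region == "CODING") "" else "0")
    v <- v[order(v$position, v$insertIndex), , drop = FALSE]
    paste(renderVariant(v), collapse = " ")
  }
  tab <- data.frame(sample_id = x@sampleID, population = x@population,
                    HVRI = vapply(x@sampleID, regionString, "", "HVRI"),
                    HVRII = vapply(x@sampleID, regionString, "", "HVRII"),
                    OTHER = vapply(x@sampleID, regionString, "", "CODING"),
                    haplogroup = x@haplogroup,
                    coding_typed = as.integer(x@codingTyped),
                    stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load the packaged El Jadida control-region survey (81 haplotypes)
#'
#' Returns the 81 El Jadida (Morocco) haplotypes with their published
#' haplogroup labels: HVRI and HVRII variant strings for all samples plus the
#' four coding-region segments typed in candidate H/HV samples.
#'
#' @return a \code{\linkS4class{HaplotypeSet}} of length 81.
#' @examples
#' ej <- loadElJadida()
#' length(ej)  # 81
#' @export
loadElJadida <- function() {
  path <- system.file("extdata", "eljadida_hvr.tsv", package = "mtPopGen",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .eljadidaMD5))
    stop("El Jadida fixture is corrupted (md5 ", sum, ", expected ",
         .eljadidaMD5, ")")
  hs <- readPopulationTable(path)
  if (length(hs) != 81L)
    stop("El Jadida fixture should contain 81 haplotypes, found ", length(hs))
  hs
}
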