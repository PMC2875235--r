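#' Run the full El Jadida report
#'
#' Orchestrates the packaged survey through classification, frequency
#' tabulation and the diversity/neutrality summary, writing deterministic
#' TSV outputs with a provenance header: \code{assignments.tsv} (per-sample
#' haplogroup calls), \code{diversity.tsv} (the one-row summary),
#' \code{frequencies_total.tsv} and \code{frequencies_withinL.tsv}. Any
#' stage failure aborts with a stage-named error and removes partial
#' outputs.
#'
#' @param outDir output directory (created if needed).
#' @param policy a \code{\linkS4class{DistancePolicy}}.
#' @param tree a \code{\linkS4class{MotifTree}}.
#' @param reps coalescent replicates for the neutrality p-values.
#' @param seed root seed; per-stage seeds are derived from it so the whole
#'   run is deterministic.
#' @return invisibly, a list with \code{assignments}, \code{diversity},
#'   \code{freqTotal}, \code{freqWithinL}, \code{macro}.
#' @export
runElJadidaReport <- function(outDir, policy = defaultPolicy(),
                              tree = elJadidaMotifTree(), reps = 1000L,
                              seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  header <- function(what) c(
    paste0(what, " generated by mtPopGen ",
           as.character(utils::packageVersion("mtPopGen"))),
    sprintf("policy: window %d-%d, indels %s, heteroplasmies %s",
            policy@rangeStart, policy@rangeEnd,
            if (policy@countIndels) "counted" else "excluded",
            if (policy@countAmbiguous) "counted" else "excluded"),
    paste0("seed: ", seed))
  writeTSV <- function(tab, file, what) {
    path <- file.path(outDir, file)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# ", header(what)), con)
    utils::write.table(format(tab, digits = 6, trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  ej <- stage("fixture", loadElJadida())
  assignments <- stage("classify", classifyHaplotypes(ej, tree))
  freqTotal <- stage("tabulate", tabulateHaplogroups(assignments, "total"))
  freqWithinL <- stage("tabulate", tabulateHaplogroups(assignments, "withinL"))
  macro <- as.data.frame(table(macro = assignments$macro),
                         stringsAsFactors = FALSE)
  macro$proportion <- macro$Freq / sum(macro$Freq)
  div <- stage("diversity",
               diversitySummary(ej, policy, reps = reps, seed = seed + 1L))
  stage("write", {
    writeTSV(assignments, "assignments.tsv", "haplogroup assignments")
    writeTSV(div, "diversity.tsv", "diversity summary")
    writeTSV(freqTotal, "frequencies_total.tsv", "haplogroup frequencies")
    writeTSV(freqWithinL, "frequencies_withinL.tsv", "within-L shares")
  })
  invisible(list(assignments = assignments, diversity = div,
                 freqTotal = freqTotal, freqWithinL = freqWithinL,
                 macro = macro))
}
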