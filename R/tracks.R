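#' Write genome-browser tracks from a scan
#'
#' Emits one bedGraph file per property x population (named
#' \code{<property>.<population>.bedGraph}) with the window spans and values,
#' plus a BED file of top regions per property for the chosen population.
#' Internally coordinates are 1-based closed; the emitted files follow the
#' 0-based half-open BED/bedGraph convention.  Windows with an undefined
#' value (e.g. average path length of an edgeless network) are omitted from
#' the corresponding track.  Values are written in full precision so that
#' re-parsing a track reproduces the scan values exactly.
#'
#' @param scan a scan table from \code{\link{scanGenotypeNetworks}}.
#' @param outDir output directory (created if needed).
#' @param topQuantile quantile used for the top-region BED files
#'   (default 0.999).
#' @param topPopulation population ranked in the top-region files
#'   (default \code{"GLOBAL"}, falling back to the first population present).
#' @return Character vector of files written, invisibly.
#' @export
writeTracks <- function(scan, outDir, topQuantile = 0.999,
                        topPopulation = "GLOBAL") {
  if (nrow(scan) == 0L) stop("empty scan: nothing to write")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (p in unique(scan$population)) {
    rows <- scan[scan$population == p, , drop = FALSE]
    for (prop in propertyColumns) {
      ok <- !is.na(rows[[prop]])
      f <- file.path(outDir, paste0(prop, ".", p, ".bedGraph"))
      writeLines(sprintf("%s\t%d\t%d\t%.17g", rows$chromosome[ok],
                         as.integer(rows$start[ok]) - 1L,
                         as.integer(rows$end[ok]), rows[[prop]][ok]), f)
      files <- c(files, f)
    }
  }
  if (!topPopulation %in% scan$population)
    topPopulation <- scan$population[1L]
  for (prop in propertyColumns) {
    tr <- topRegions(scan, prop, quantile = topQuantile,
                     population = topPopulation)
    f <- file.path(outDir, paste0("top_regions.", prop, ".bed"))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.17g", tr$chromosome,
                       as.integer(tr$start) - 1L, as.integer(tr$end),
                       paste0(prop, "_rank", seq_len(nrow(tr))), tr$value), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write a scan table as TSV
#'
#' @param scan a scan table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeScanTsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
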