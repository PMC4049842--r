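#' Load a genetic map
#'
#' Reads a three-column whitespace-separated table (chromosome, position in
#' bp, cumulative genetic distance in cM), as distributed with phased
#' reference panels.
#'
#' @param path map file; a header line is auto-detected.
#' @return A data frame with columns \code{chrom}, \code{pos}, \code{cM},
#'   sorted by chromosome and position.
#' @export
loadGeneticMap <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\S+\\s+[0-9]+\\s+[-0-9.eE]+\\s*$", first)
  map <- utils::read.table(path, header = hasHeader, stringsAsFactors = FALSE)
  names(map)[1:3] <- c("chrom", "pos", "cM")
  map[order(map$chrom, map$pos), c("chrom", "pos", "cM")]
}

#' Interpolate cumulative genetic-map position
#'
#' Linear interpolation of cumulative cM at arbitrary base-pair positions;
#' positions outside the map range take the nearest endpoint value
#' (extrapolation is flat) and are counted.
#'
#' @param map data frame as returned by \code{\link{loadGeneticMap}}.
#' @param chrom chromosome of the query positions.
#' @param positions base-pair positions.
#' @return Numeric vector of cumulative cM; the number of extrapolated query
#'   positions is attached as attribute \code{"n_extrapolated"}.
#' @export
interpolateGeneticMap <- function(map, chrom, positions) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) == 0L)
    stop("genetic map has no entries for chromosome ", chrom)
  if (nrow(sub) == 1L) {
    out <- rep(sub$cM, length(positions))
    nex <- sum(positions != sub$pos)
  } else {
    out <- stats::approx(sub$pos, sub$cM, xout = positions, rule = 2,
                         ties = "ordered")$y
    nex <- sum(positions < min(sub$pos) | positions > max(sub$pos))
  }
  if (nex > 0)
    message(nex, " position(s) outside the genetic map; nearest-endpoint value used")
  attr(out, "n_extrapolated") <- nex
  out
}
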