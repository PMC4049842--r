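#' Read an ms-style haplotype block
#'
#' Parses the classic coalescent-simulator text format: a \code{segsites:}
#' line, a \code{positions:} line of fractional coordinates in [0, 1], and one
#' 0/1 row per haplotype.  Only the first replicate block of a file is read.
#' Positions are scaled to \code{regionLength} base pairs and de-duplicated to
#' strictly increasing integer coordinates.
#'
#' @param path file containing an ms-style block.
#' @param populationSizes haplotype counts per population, in row-block order;
#'   must sum to the number of haplotype rows.
#' @param regionLength length in bp of the simulated region used to scale the
#'   fractional positions.
#' @param labels population labels (default \code{P0, P1, ...}).
#' @param chromosome chromosome name for the resulting sites.
#' @return A \linkS4class{HaplotypeMatrix}.
#' @export
loadMsMatrix <- function(path, populationSizes, regionLength = 1e6,
                         labels = paste0("P", seq_along(populationSizes) - 1L),
                         chromosome = "sim") {
  lines <- readLines(path)
  segLine <- grep("^segsites:", lines)[1L]
  if (is.na(segLine)) stop("not an ms-style file: no 'segsites:' line")
  nseg <- as.integer(sub("^segsites:\\s*", "", lines[segLine]))
  if (nseg == 0L)
    stop("ms block has zero segregating sites")
  posLine <- grep("^positions:", lines)[1L]
  pos <- as.numeric(strsplit(sub("^positions:\\s*", "", lines[posLine]),
                             "\\s+")[[1L]])
  if (length(pos) != nseg) stop("positions line does not match segsites")
  body <- lines[seq(posLine + 1L, length(lines))]
  body <- body[cumsum(!grepl("^[01]+$", body)) == 0L]  # stop at first non-row
  if (length(body) == 0L) stop("no haplotype rows found")
  lens <- unique(nchar(body))
  if (length(lens) != 1L || lens != nseg)
    stop("inconsistent haplotype row lengths in ms block")
  if (sum(populationSizes) != length(body))
    stop("sum(populationSizes) (", sum(populationSizes),
         ") does not match the haplotype count (", length(body), ")")
  alleles <- matrix(as.integer(unlist(strsplit(body, "", fixed = TRUE))),
                    nrow = length(body), byrow = TRUE)
  bp <- as.integer(round(pos * regionLength))
  bp <- pmax(bp, 1L)
  while (any(diff(bp) <= 0L)) bp[c(FALSE, diff(bp) <= 0L)] <-
      bp[c(FALSE, diff(bp) <= 0L)] + 1L
  HaplotypeMatrix(alleles, positions = bp, chromosome = chromosome,
                  populations = rep(labels, times = populationSizes))
}

#' Write a HaplotypeMatrix as an ms-style block
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param path output file.
#' @param regionLength region length in bp used to express positions as
#'   fractions.
#' @return \code{path}, invisibly.
#' @export
writeMsMatrix <- function(x, path, regionLength = max(sitePositions(x), 1)) {
  a <- alleleMatrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("genonet ms export", paste(nHaplotypes(x), 1L), "",
               "//",
               paste0("segsites: ", nSites(x)),
               paste("positions:",
                     paste(sprintf("%.6f", sitePositions(x) / regionLength),
                           collapse = " "))), con)
  writeLines(apply(a, 1L, paste, collapse = ""), con)
  invisible(path)
}
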