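#' Load phased haplotypes from a VCF
#'
#' Reads a VCF (plain or bgzipped) of phased genotypes and encodes the
#' haplotypes as a \linkS4class{HaplotypeMatrix}.  Site filters follow the
#' genotype-network protocol: multiallelic (e.g. triallelic) records and
#' non-SNV records are removed; sites with any unphased ("/"-separated) or
#' missing (".") genotype among the retained samples are dropped and counted;
#' the minor-allele-frequency filter is then applied under the chosen mode.
#' The two haplotypes of each diploid sample become separate rows, ordered
#' sample by sample, left haplotype then right.
#'
#' @param path VCF file.
#' @param mafThreshold minimum minor allele frequency (use 0 to disable).
#' @param mafMode \code{"global"} (MAF computed over all haplotypes pooled) or
#'   \code{"any_population"} (site kept if its MAF reaches the threshold in at
#'   least one population).  Required whenever \code{mafThreshold > 0}; there
#'   is deliberately no default.
#' @param populations named character vector mapping sample name to population
#'   label, or the path of a two-column (sample, label) whitespace-separated
#'   file.  Samples absent from the map are not loaded.  \code{NULL} loads all
#'   samples under the label \code{"ALL"}.
#' @param annotations optional per-SNV functional annotation: a data frame (or
#'   file) with columns chromosome, position and class
#'   (\code{coding}/\code{noncoding}/\code{none}); unlisted sites get
#'   \code{"none"}.
#' @param minInfoDepth optional minimum value of an INFO \code{DP} field;
#'   sites below it are dropped.  Off (\code{NULL}) by default since
#'   per-site coverage is not standardised across VCF producers.
#' @return A \linkS4class{HaplotypeMatrix}; counts of sites dropped by each
#'   filter are in \code{metadata()$filterCounts}.  If no site survives, a
#'   zero-site matrix is returned with a warning.
#' @export
loadPhasedVcf <- function(path, mafThreshold, mafMode, populations = NULL,
                          annotations = NULL, minInfoDepth = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  if (missing(mafThreshold)) stop("'mafThreshold' is required (use 0 to disable)")
  if (mafThreshold > 0 && missing(mafMode))
    stop("'mafMode' must be chosen explicitly ('global' or 'any_population')")
  if (mafThreshold == 0 && missing(mafMode)) mafMode <- "global"
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(v@gt)[-1L]
  colnames(gt) <- samples

  popmap <- resolvePopulationMap(populations, samples)
  keepSamples <- intersect(samples, names(popmap))
  if (length(keepSamples) == 0L) stop("no sample matches the population map")
  gt <- gt[, keepSamples, drop = FALSE]

  counts <- list(multiallelic = 0L, non_snv = 0L, unphased = 0L,
                 missing = 0L, low_depth = 0L, low_maf = 0L)
  nuc <- c("A", "C", "G", "T")
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  counts$multiallelic <- sum(multi)
  snv <- !multi & toupper(ref) %in% nuc & toupper(alt) %in% nuc
  counts$non_snv <- sum(!snv & !multi)
  keep <- snv

  if (!is.null(minInfoDepth)) {
    dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9.]+).*", "\\1",
                                          fix[, "INFO"])))
    lowdp <- keep & (is.na(dp) | dp < minInfoDepth)
    counts$low_depth <- sum(lowdp)
    keep <- keep & !lowdp
  }

  hasMissing <- keep & apply(gt, 1L, function(g) anyNA(g) ||
                               any(grepl(".", g, fixed = TRUE)))
  counts$missing <- sum(hasMissing)
  keep <- keep & !hasMissing
  unphased <- keep & apply(gt, 1L, function(g) !all(grepl("|", g, fixed = TRUE)))
  counts$unphased <- sum(unphased)
  keep <- keep & !unphased

  if (!any(keep)) {
    warning("no site survived the filters; returning an empty HaplotypeMatrix")
    hm <- HaplotypeMatrix(matrix(integer(0), nrow = 2L * length(keepSamples)),
                          positions = numeric(0),
                          populations = rep(popmap[keepSamples], each = 2L),
                          samples = rep(keepSamples, each = 2L),
                          metadata = list(filterCounts = counts))
    return(hm)
  }

  gtk <- gt[keep, , drop = FALSE]
  left <- substr(gtk, 1L, 1L)
  right <- substr(gtk, 3L, 3L)
  ns <- nrow(gtk)
  nsamp <- length(keepSamples)
  alleles <- matrix(0L, nrow = 2L * nsamp, ncol = ns)
  alleles[seq(1L, 2L * nsamp, by = 2L), ] <- t(matrix(as.integer(left), ns))
  alleles[seq(2L, 2L * nsamp, by = 2L), ] <- t(matrix(as.integer(right), ns))

  hm <- HaplotypeMatrix(alleles,
                        positions = as.numeric(fix[keep, "POS"]),
                        chromosome = fix[keep, "CHROM"],
                        ref = toupper(ref[keep]), alt = toupper(alt[keep]),
                        populations = rep(unname(popmap[keepSamples]), each = 2L),
                        samples = rep(keepSamples, each = 2L),
                        metadata = list(filterCounts = counts))
  if (!is.null(annotations)) hm <- annotateSites(hm, annotations)
  if (mafThreshold > 0) {
    hm <- mafFilter(hm, mafThreshold, mafMode)
    if (nSites(hm) == 0L)
      warning("no site survived the MAF filter; returning an empty HaplotypeMatrix")
  }
  hm
}

resolvePopulationMap <- function(populations, samples) {
  if (is.null(populations))
    return(stats::setNames(rep("ALL", length(samples)), samples))
  if (is.character(populations) && is.null(names(populations)) &&
      length(populations) == 1L && file.exists(populations)) {
    tab <- utils::read.table(populations, header = FALSE,
                             stringsAsFactors = FALSE)
    populations <- stats::setNames(tab[[2L]], tab[[1L]])
  }
  if (is.null(names(populations)))
    stop("'populations' must be a named sample->label vector or a two-column file")
  bad <- setdiff(names(populations), samples)
  if (length(bad))
    stop("samples in the population map missing from the VCF header: ",
         paste(bad, collapse = ", "))
  populations
}

#' Attach per-SNV functional annotation classes
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param annotations data frame (or whitespace-separated file) with columns
#'   chromosome, position, class; class is one of \code{coding},
#'   \code{noncoding}, \code{none}.
#' @return \code{x} with the \code{annotation} column of its site ranges set;
#'   sites not listed keep/get \code{"none"}.
#' @export
annotateSites <- function(x, annotations) {
  if (is.character(annotations))
    annotations <- utils::read.table(annotations, header = FALSE,
                                     stringsAsFactors = FALSE,
                                     col.names = c("chrom", "pos", "class"))
  names(annotations)[1:3] <- c("chrom", "pos", "class")
  key <- paste(as.character(seqnames(rowRanges(x))), sitePositions(x))
  akey <- paste(as.character(annotations$chrom), annotations$pos)
  m <- match(key, akey)
  cls <- ifelse(is.na(m), "none", as.character(annotations$class)[m])
  if (!all(cls %in% c("coding", "noncoding", "none")))
    stop("annotation classes must be coding/noncoding/none")
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$annotation <- cls
  x
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' Emits a minimal VCF v4.2 with one diploid sample per consecutive haplotype
#' pair and pipe-separated (phased) genotypes.  Reloading the file with
#' \code{\link{loadPhasedVcf}} (filters disabled) reproduces the allele
#' matrix exactly.
#'
#' @param x a \linkS4class{HaplotypeMatrix} with an even number of haplotypes.
#' @param path output file (plain text).
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(x, path) {
  nh <- nHaplotypes(x)
  if (nh %% 2L != 0L)
    stop("an even number of haplotypes is required to form diploid samples")
  a <- alleleMatrix(x)
  samp <- colData(x)$sample
  sampNames <- samp[seq(1L, nh, by = 2L)]
  if (anyDuplicated(sampNames))
    sampNames <- sprintf("S%04d", seq_len(nh / 2L))
  rr <- rowRanges(x)
  mc <- S4Vectors::mcols(rr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=genonet",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampNames), collapse = "\t")), con)
  if (nSites(x) > 0) {
    gtcols <- vapply(seq_len(nh / 2L), function(s) {
      paste0(a[2L * s - 1L, ], "|", a[2L * s, ])
    }, character(nSites(x)))
    gtcols <- matrix(gtcols, nrow = nSites(x))
    lines <- paste(as.character(seqnames(rr)), start(rr),
                   paste0("snv", seq_len(nSites(x))), mc$ref, mc$alt,
                   ".", "PASS", ".", "GT",
                   apply(gtcols, 1L, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
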