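#' Generate the small plain-text fixtures used in examples and tests
#'
#' Writes deterministic toy inputs to \code{outDir}:
#' \describe{
#'   \item{\code{toy.vcf}}{5 phased SNVs x 10 diploid samples (20 haplotypes)
#'     in a 5-site genotype space, with hand-chosen genotypes.}
#'   \item{\code{filters.vcf}}{sites exercising every loader filter: one
#'     triallelic, one indel, one with an unphased genotype, one with a
#'     missing call, one singleton (global MAF 0.05, dropped by any stricter
#'     threshold), plus two clean sites.}
#'   \item{\code{populations.txt}}{sample-to-population map (two columns).}
#'   \item{\code{annotations.tsv}}{per-SNV functional classes for toy.vcf.}
#'   \item{\code{map.tsv}}{toy genetic map (chrom, pos, cumulative cM).}
#'   \item{\code{mask.bed}}{one exclusion interval overlapping toy.vcf.}
#'   \item{\code{ms_example.txt}}{a 6-haplotype ms-style block.}
#' }
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed (fixtures are fully deterministic given it).
#' @return Named character vector of the files written, invisibly.
#' @export
makeFixtures <- function(outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c()

  # toy.vcf: haplotype strings chosen to give small, hand-checkable networks
  haps <- withSeed(seed, {
    base <- c("00000", "00001", "01001", "00011", "01100", "00000",
              "00001", "00000", "10000", "00101")
    sample(rep(base, 2L))
  })
  alleles <- matrix(as.integer(unlist(strsplit(haps, ""))), byrow = TRUE,
                    nrow = length(haps))
  hm <- HaplotypeMatrix(alleles,
                        positions = c(1200L, 3400L, 5100L, 8800L, 9900L),
                        chromosome = "chr1",
                        ref = c("A", "C", "G", "T", "A"),
                        alt = c("G", "T", "A", "C", "T"),
                        populations = rep(c("AFR", "EUR"), each = 10L),
                        samples = rep(sprintf("S%02d", 1:10), each = 2L))
  toy <- file.path(outDir, "toy.vcf")
  writePhasedVcf(hm, toy)
  files["toy_vcf"] <- toy

  pops <- file.path(outDir, "populations.txt")
  writeLines(sprintf("S%02d\t%s", 1:10, rep(c("AFR", "EUR"), each = 5L)),
             pops)
  files["populations"] <- pops

  ann <- file.path(outDir, "annotations.tsv")
  writeLines(c("chr1\t1200\tcoding", "chr1\t3400\tnone",
               "chr1\t5100\tnoncoding", "chr1\t8800\tcoding"), ann)
  files["annotations"] <- ann

  gmap <- file.path(outDir, "map.tsv")
  writeLines(c("chr1\t1000\t0.00", "chr1\t5000\t0.40", "chr1\t10000\t1.50"),
             gmap)
  files["map"] <- gmap

  mask <- file.path(outDir, "mask.bed")
  writeLines("chr1\t5000\t5200", mask)
  files["mask"] <- mask

  # filters.vcf: header shared with toy.vcf sample names
  filt <- file.path(outDir, "filters.vcf")
  gtRow <- function(gt) paste(rep(gt, 10L), collapse = "\t")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=genonet-fixtures",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%02d", 1:10)), collapse = "\t"),
    paste("chr1", 100, "clean1", "A", "T", ".", "PASS", ".", "GT",
          paste(rep(c("0|1", "0|0"), 5L), collapse = "\t"), sep = "\t"),
    paste("chr1", 200, "triallelic", "A", "T,G", ".", "PASS", ".", "GT",
          gtRow("0|1"), sep = "\t"),
    paste("chr1", 300, "indel", "AT", "A", ".", "PASS", ".", "GT",
          gtRow("0|1"), sep = "\t"),
    paste("chr1", 400, "unphased", "C", "G", ".", "PASS", ".", "GT",
          paste(c(rep("0|1", 9L), "0/1"), collapse = "\t"), sep = "\t"),
    paste("chr1", 500, "missing", "G", "A", ".", "PASS", ".", "GT",
          paste(c(rep("0|1", 9L), ".|."), collapse = "\t"), sep = "\t"),
    paste("chr1", 600, "rare", "T", "C", ".", "PASS", ".", "GT",
          paste(c("0|1", rep("0|0", 9L)), collapse = "\t"), sep = "\t"),
    paste("chr1", 700, "clean2", "T", "A", ".", "PASS", ".", "GT",
          paste(rep(c("1|1", "0|0"), 5L), collapse = "\t"), sep = "\t")),
    filt)
  files["filters_vcf"] <- filt

  msf <- file.path(outDir, "ms_example.txt")
  writeLines(c("ms 6 1", "1 2 3", "", "//", "segsites: 4",
               "positions: 0.1000 0.2500 0.6000 0.9000",
               "0000", "0001", "0011", "0001", "1000", "0000"), msf)
  files["ms"] <- msf

  invisible(files)
}
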