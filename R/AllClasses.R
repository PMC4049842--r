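#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

setOldClass("igraph")

#' HaplotypeMatrix: phased binary haplotypes over biallelic SNV sites
#'
#' A \code{HaplotypeMatrix} holds a sample of phased haplotypes over an
#' ordered set of biallelic single-nucleotide variant (SNV) sites.  It extends
#' \link[SummarizedExperiment]{RangedSummarizedExperiment}: rows are sites
#' (with position, reference/alternative allele and an optional functional
#' annotation class in \code{rowRanges}), columns are haplotypes (two per
#' diploid individual, treated as independent entities), and the single
#' \code{"alleles"} assay stores 0 for the reference allele and 1 for the
#' alternative allele.  Per-haplotype population labels live in
#' \code{colData(x)$population}.
#'
#' Use the \code{\link{HaplotypeMatrix}} constructor rather than \code{new()};
#' it takes the haplotype-major orientation (one row per haplotype) used
#' throughout the package interface and transposes internally.
#'
#' @seealso \code{\link{HaplotypeMatrix}}, \code{\link{loadPhasedVcf}},
#'   \code{\link{genotypeStrings}}, \code{\link{mafFilter}}
#' @export
setClass("HaplotypeMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  if (!"alleles" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'alleles' is required")
  else {
    a <- SummarizedExperiment::assay(object, "alleles")
    if (!is.integer(a) || any(is.na(a)) || any(a != 0L & a != 1L))
      msg <- c(msg, "allele entries must be 0 or 1 with no missing values")
  }
  if (is.null(colData(object)$population))
    msg <- c(msg, "colData must carry a 'population' column")
  rr <- rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
  if (length(rr) > 1) {
    bychr <- split(start(rr), as.character(seqnames(rr)))
    if (!all(vapply(bychr, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeNetwork: Hamming-distance-1 graph of distinct genotype strings
#'
#' Nodes are the distinct binary genotype strings observed in a sample of
#' haplotypes over \code{k} SNV sites; an undirected edge joins two nodes if
#' and only if their strings differ at exactly one position (Hamming distance
#' one, a single mutational step).  The graph is simple and unweighted.  The
#' number of haplotypes carrying each node is kept in \code{nodeCounts} but
#' does not weight any network property.
#'
#' @slot graph an \pkg{igraph} graph; vertex attribute \code{name} holds the
#'   genotype string.
#' @slot nodeCounts named integer vector: haplotype count per node.
#' @slot k integer: string length (number of SNV sites).
#' @slot nHaplotypes integer: number of input haplotypes
#'   (\code{sum(nodeCounts)}).
#'
#' @seealso \code{\link{buildNetwork}}, \code{\link{networkProperties}}
#' @export
setClass("GenotypeNetwork",
         representation(graph = "igraph", nodeCounts = "integer",
                        k = "integer", nHaplotypes = "integer"))

setValidity("GenotypeNetwork", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (is.null(names(object@nodeCounts)))
    msg <- c(msg, "nodeCounts must be named by genotype string")
  if (igraph::vcount(object@graph) != length(object@nodeCounts))
    msg <- c(msg, "graph order must equal the number of distinct genotypes")
  if (sum(object@nodeCounts) != object@nHaplotypes)
    msg <- c(msg, "nodeCounts must sum to the number of input haplotypes")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: demography, sweep and sampling parameters
#'
#' Parameters of the forward-in-time Wright-Fisher simulator, in natural
#' (unscaled) units.  The demography is a clean three-population split:
#' an ancestral (African-like) population splits into Africans and an
#' out-of-Africa branch \code{ooaSplitGenerations} ago; the out-of-Africa
#' branch splits into Europeans and Asians \code{eurasianSplitGenerations}
#' ago.  Population sizes are diploid effective sizes, constant within an
#' epoch.  \code{scale} rescales the model for tractability (sizes and times
#' divided, mutation/recombination/selection multiplied), preserving the
#' population-scaled parameters theta = 4*N*mu, rho = 4*N*r and
#' sigma = 2*N*s.
#'
#' The optional \code{sweep} list activates a selective sweep: a focal allele
#' introduced in the ancestral population \code{introGenerations} ago is
#' conditioned on segregating, and multiplicative selection with coefficient
#' \code{selectionCoefficient} is switched on at the latest time that still
#' lets the allele reach \code{finalFrequency} (global frequency across the
#' pooled populations) by sampling time; trajectories that miss the target
#' band are retried.
#'
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateNeutral}},
#'   \code{\link{simulateSweep}}
#' @export
setClass("SimulationConfig",
         representation(nHaplotypesPerPop = "integer",
                        populations = "character",
                        neAncestral = "numeric",
                        neAfrican = "numeric",
                        neOoaBottleneck = "numeric",
                        neEuropean = "numeric",
                        neAsian = "numeric",
                        neAfricanPresent = "numeric",
                        neEuropeanPresent = "numeric",
                        neAsianPresent = "numeric",
                        growthStartGenerations = "numeric",
                        ooaSplitGenerations = "numeric",
                        eurasianSplitGenerations = "numeric",
                        burnInFactor = "numeric",
                        regionLengthBp = "numeric",
                        mutationRate = "numeric",
                        recombinationRate = "numeric",
                        scale = "numeric",
                        sweep = "list",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@nHaplotypesPerPop < 2L))
    msg <- c(msg, "at least two haplotypes per population are required")
  if (length(object@populations) != length(object@nHaplotypesPerPop) &&
      length(object@nHaplotypesPerPop) != 1L)
    msg <- c(msg, "nHaplotypesPerPop must have length 1 or one per population")
  if (object@ooaSplitGenerations > 0 &&
      object@eurasianSplitGenerations >= object@ooaSplitGenerations)
    msg <- c(msg, "the Eurasian split must be more recent than the out-of-Africa split")
  if (length(object@sweep)) {
    s <- object@sweep
    if (is.null(s$selectionCoefficient) || s$selectionCoefficient < 0)
      msg <- c(msg, "sweep$selectionCoefficient must be >= 0")
    if (is.null(s$finalFrequency) || s$finalFrequency <= 0 || s$finalFrequency > 1)
      msg <- c(msg, "sweep$finalFrequency must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
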