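#' Construct a HaplotypeMatrix
#'
#' @param alleles integer matrix of 0/1 with one row per haplotype and one
#'   column per SNV site (0 = reference allele, 1 = alternative allele).
#' @param positions 1-based base-pair positions, one per site, strictly
#'   increasing within a chromosome.
#' @param chromosome chromosome identifier(s); length 1 or one per site.
#' @param populations population label per haplotype row (recycled if length 1).
#' @param ref,alt single-nucleotide reference / alternative alleles per site.
#' @param annotation functional annotation class per site: \code{"coding"},
#'   \code{"noncoding"} or \code{"none"}.
#' @param samples sample identifier per haplotype row (two rows per diploid
#'   individual when derived from VCF).
#' @param metadata named list stored in \code{metadata()} (e.g. filter counts).
#'
#' @return A \linkS4class{HaplotypeMatrix}.
#' @examples
#' hm <- HaplotypeMatrix(rbind(c(0L, 1L, 1L), c(0L, 0L, 1L)),
#'                       positions = c(101, 205, 330),
#'                       populations = c("AFR", "EUR"))
#' genotypeStrings(hm)
#' @export
HaplotypeMatrix <- function(alleles, positions, chromosome = "1",
                            populations = "ALL", ref = NULL, alt = NULL,
                            annotation = NULL, samples = NULL,
                            metadata = list()) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  ns <- ncol(alleles)
  nh <- nrow(alleles)
  if (length(positions) != ns)
    stop("'positions' must have one entry per site (", ns, ")")
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("T", ns)
  if (is.null(annotation)) annotation <- rep("none", ns)
  annotation <- as.character(annotation)
  if (length(annotation) == 1L) annotation <- rep(annotation, ns)
  if (!all(annotation %in% c("coding", "noncoding", "none")))
    stop("annotation classes must be 'coding', 'noncoding' or 'none'")
  populations <- rep_len(as.character(populations), nh)
  if (is.null(samples)) samples <- sprintf("hap%03d", seq_len(nh))
  rr <- GRanges(rep_len(as.character(chromosome), ns),
                IRanges(as.integer(round(positions)), width = 1L),
                ref = as.character(ref), alt = as.character(alt),
                annotation = annotation)
  cd <- DataFrame(sample = as.character(samples), population = populations,
                  row.names = make.unique(paste0(samples, "_", seq_len(nh))))
  se <- SummarizedExperiment(assays = list(alleles = t(alleles)),
                             rowRanges = rr, colData = cd,
                             metadata = metadata)
  new("HaplotypeMatrix", se)
}

#' Accessors for HaplotypeMatrix
#'
#' \code{nHaplotypes} and \code{nSites} count haplotype rows and SNV sites;
#' \code{alleleMatrix} returns the haplotype-major 0/1 matrix (one row per
#' haplotype); \code{populationLabels} the per-haplotype population labels;
#' \code{sitePositions} the 1-based positions; \code{annotationClass} the
#' per-site functional class.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @return See individual descriptions.
#' @name HaplotypeMatrix-accessors
NULL

#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("nHaplotypes", "HaplotypeMatrix", function(x) ncol(x))

#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("nSites", "HaplotypeMatrix", function(x) nrow(x))

#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("alleleMatrix", "HaplotypeMatrix",
          function(x) unname(t(SummarizedExperiment::assay(x, "alleles"))))

#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("populationLabels", "HaplotypeMatrix",
          function(x) as.character(colData(x)$population))

#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("sitePositions", "HaplotypeMatrix",
          function(x) GenomicRanges::start(rowRanges(x)))

#' @rdname HaplotypeMatrix-accessors
#' @export
setMethod("annotationClass", "HaplotypeMatrix",
          function(x) as.character(S4Vectors::mcols(rowRanges(x))$annotation))

setMethod("show", "HaplotypeMatrix", function(object) {
  pops <- table(populationLabels(object))
  cat("HaplotypeMatrix:", nHaplotypes(object), "haplotypes x",
      nSites(object), "SNV sites\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
  if (nSites(object) > 0) {
    chr <- as.character(seqnames(rowRanges(object)))
    cat("span:", chr[1], ":", min(sitePositions(object)), "-",
        max(sitePositions(object)), "\n", sep = "")
  }
})

#' Encode haplotypes as binary genotype strings
#'
#' Each haplotype over the selected site range becomes a string of "0"
#' (reference allele) and "1" (alternative allele).  Duplicate haplotypes
#' yield duplicate strings; order follows the haplotype rows.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param siteRange integer vector of site indices; must be a non-empty,
#'   strictly forward range within bounds.
#' @return Character vector, one string of length \code{length(siteRange)} per
#'   haplotype.
#' @export
genotypeStrings <- function(x, siteRange = seq_len(nSites(x))) {
  stopifnot(is(x, "HaplotypeMatrix"))
  if (length(siteRange) == 0L)
    stop("empty site range")
  siteRange <- as.integer(siteRange)
  if (any(diff(siteRange) <= 0L))
    stop("site ranges are forward only (strictly increasing indices)")
  if (min(siteRange) < 1L || max(siteRange) > nSites(x))
    stop("site range out of bounds")
  a <- SummarizedExperiment::assay(x, "alleles")  # sites x haplotypes
  cols <- lapply(siteRange, function(i) a[i, ])
  do.call(paste0, cols)
}

#' Minor-allele-frequency filter
#'
#' Removes SNV sites whose minor allele frequency falls below \code{threshold}.
#' Two rules are supported because different analyses call for different
#' pooling: \code{"global"} computes the MAF over all haplotypes pooled;
#' \code{"any_population"} keeps a site if its MAF reaches the threshold in at
#' least one population (i.e. drops sites that are low-frequency in all
#' populations).  The mode must be chosen explicitly.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param threshold minimum minor allele frequency (fraction), e.g. 0.01.
#' @param mode \code{"global"} or \code{"any_population"}.
#' @return A filtered \linkS4class{HaplotypeMatrix}; the number of sites
#'   removed is appended to \code{metadata(x)$filterCounts$low_maf}.
#' @export
mafFilter <- function(x, threshold, mode = c("global", "any_population")) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 0.5)
    stop("'threshold' must be a fraction in [0, 0.5]")
  a <- SummarizedExperiment::assay(x, "alleles")
  nh <- ncol(a)
  if (mode == "global") {
    f <- rowSums(a) / nh
    keep <- pmin(f, 1 - f) >= threshold
  } else {
    pops <- populationLabels(x)
    mafs <- vapply(split(seq_len(nh), pops), function(idx) {
      f <- rowSums(a[, idx, drop = FALSE]) / length(idx)
      pmin(f, 1 - f)
    }, numeric(nrow(a)))
    mafs <- matrix(mafs, nrow = nrow(a))
    keep <- apply(mafs, 1L, max) >= threshold
  }
  out <- x[keep, ]
  fc <- metadata(x)$filterCounts
  if (is.null(fc)) fc <- list()
  fc$low_maf <- (fc$low_maf %||% 0L) + sum(!keep)
  metadata(out)$filterCounts <- fc
  out
}

#' Subsample haplotypes
#'
#' Draws a random subset of haplotypes without replacement, by default
#' stratified within each population (\code{n} haplotypes from each).  In
#' nested mode, subsamples of increasing size drawn under the same seed are
#' nested (a size-1000 draw is a subset of the size-2000 draw), which makes
#' vertex counts exactly monotone in sample size rather than only in
#' expectation.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param n haplotypes to draw per population (or in total when
#'   \code{pooled = TRUE}).
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @param pooled ignore population labels and draw \code{n} from all rows.
#' @param nested use seeded per-population permutations and take the first
#'   \code{n} entries, so draws are nested across sizes.
#' @return A \linkS4class{HaplotypeMatrix} with the drawn rows, in original
#'   row order.
#' @export
subsampleHaplotypes <- function(x, n, seed = 1L, pooled = FALSE,
                                nested = FALSE) {
  stopifnot(is(x, "HaplotypeMatrix"))
  pops <- populationLabels(x)
  idx <- withSeed(seed, {
    if (pooled) {
      if (n > nHaplotypes(x)) stop("n exceeds the number of haplotypes")
      sample(nHaplotypes(x), n)
    } else {
      groups <- split(seq_along(pops), pops)
      unlist(lapply(groups, function(g) {
        if (n > length(g))
          stop("n exceeds the haplotype count of a population (",
               length(g), ")")
        if (nested) g[order(sample.int(length(g)))[seq_len(n)]]
        else sample(g, n)
      }), use.names = FALSE)
    }
  })
  x[, sort(idx)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Internal helper: runs \code{expr} with \code{set.seed(seed)} and restores
#' the caller's RNG state afterwards.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
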