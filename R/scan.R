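propertyColumns <- c("n_vertices", "avg_path_length", "n_components",
                     "avg_degree", "vertices_per_component")

#' Enumerate sliding windows of a fixed SNV count
#'
#' Windows cover \code{k} consecutive SNV sites and advance by \code{step}
#' sites; they never span chromosome boundaries, and a trailing partial window
#' is discarded.  Window spans are reported as the closed interval from the
#' first to the last SNV position (1-based).
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param k SNVs per window (>= 2); the scan default is 11.
#' @param step SNVs between successive window starts (>= 1).
#' @return Data frame with one row per window: \code{chromosome},
#'   \code{first_site} (global site index), \code{start}, \code{end},
#'   \code{span_bp}, \code{n_snvs}.  Empty (with a warning) if no chromosome
#'   holds \code{k} sites.
#' @export
iterWindows <- function(x, k = 11L, step = 1L) {
  stopifnot(k >= 2L, step >= 1L)
  chrom <- as.character(seqnames(rowRanges(x)))
  pos <- sitePositions(x)
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < k) next
    firsts <- idx[seq(1L, length(idx) - k + 1L, by = step)]
    out[[ch]] <- data.frame(chromosome = ch, first_site = firsts,
                            start = pos[firsts], end = pos[firsts + k - 1L],
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    warning("no chromosome holds ", k, " SNV sites; zero windows")
    return(data.frame(chromosome = character(0), first_site = integer(0),
                      start = numeric(0), end = numeric(0),
                      span_bp = numeric(0), n_snvs = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$span_bp <- res$end - res$start
  res$n_snvs <- as.integer(k)
  res
}

#' Classify a window by the functional annotation of its SNVs
#'
#' @param classes per-SNV annotation classes (\code{coding},
#'   \code{noncoding}, \code{none}).
#' @return \code{"coding"} if at least one coding and no noncoding SNV,
#'   \code{"noncoding"} for the converse, \code{"both"} if both kinds occur,
#'   \code{"no_annotation"} if every SNV is unannotated.
#' @export
classifyWindowAnnotation <- function(classes) {
  hasCod <- any(classes == "coding")
  hasNon <- any(classes == "noncoding")
  if (hasCod && hasNon) "both"
  else if (hasCod) "coding"
  else if (hasNon) "noncoding"
  else "no_annotation"
}

#' Sliding-window genotype-network scan
#'
#' For every window of \code{k} consecutive SNVs, builds one genotype network
#' per population plus one for all haplotypes pooled (\code{GLOBAL}), and
#' computes the network properties.  When a genetic map is supplied, the
#' cumulative cM distance between the first and last SNV of each window is
#' attached as \code{recomb_cM}.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param k,step window size and stride in SNVs (defaults 11 and 1).
#' @param geneticMap optional map (data frame from
#'   \code{\link{loadGeneticMap}} or a file path).
#' @param includeGlobal add the pooled \code{GLOBAL} rows (on by default).
#' @return A scan table (class \code{genonetScan}): one row per window x
#'   population with the window columns of \code{\link{iterWindows}},
#'   \code{recomb_cM}, \code{annotation_class}, \code{population}, and the
#'   five property columns.  Site coordinates travel along in
#'   \code{attr(, "sites")} so masks can be applied later.
#' @export
scanGenotypeNetworks <- function(x, k = 11L, step = 1L, geneticMap = NULL,
                                 includeGlobal = TRUE) {
  wins <- iterWindows(x, k, step)
  pops <- populationLabels(x)
  if (is.character(geneticMap) && length(geneticMap) == 1L)
    geneticMap <- loadGeneticMap(geneticMap)
  a <- SummarizedExperiment::assay(x, "alleles")
  ann <- annotationClass(x)
  groups <- split(seq_along(pops), pops)
  popNames <- names(groups)
  if (includeGlobal) popNames <- c(popNames, "GLOBAL")

  recomb <- rep(NA_real_, nrow(wins))
  if (!is.null(geneticMap) && nrow(wins) > 0) {
    for (ch in unique(wins$chromosome)) {
      sel <- wins$chromosome == ch
      cm1 <- interpolateGeneticMap(geneticMap, ch, wins$start[sel])
      cm2 <- interpolateGeneticMap(geneticMap, ch, wins$end[sel])
      recomb[sel] <- as.numeric(cm2) - as.numeric(cm1)
    }
  }

  rows <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    sites <- wins$first_site[w] + 0:(k - 1L)
    strings <- do.call(paste0, lapply(sites, function(i) a[i, ]))
    props <- lapply(popNames, function(p) {
      s <- if (p == "GLOBAL") strings else strings[groups[[p]]]
      networkProperties(buildNetwork(s))
    })
    props <- do.call(rbind, props)
    rows[[w]] <- cbind(wins[rep(w, length(popNames)), , drop = FALSE],
                       recomb_cM = recomb[w],
                       annotation_class = classifyWindowAnnotation(ann[sites]),
                       population = popNames, props,
                       stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    cbind(wins[0, ], recomb_cM = numeric(0), annotation_class = character(0),
          population = character(0))
  rownames(res) <- NULL
  attr(res, "sites") <- data.frame(
    chrom = as.character(seqnames(rowRanges(x))), pos = sitePositions(x),
    stringsAsFactors = FALSE)
  attr(res, "k") <- as.integer(k)
  class(res) <- c("genonetScan", "data.frame")
  res
}

#' Remove windows intersecting exclusion masks
#'
#' Drops every scan row whose window contains at least one SNV inside any mask
#' interval (assembly gaps, centromeres, telomeres, ...).  Masks follow the
#' BED convention: 0-based, half-open.
#'
#' @param scan a scan table from \code{\link{scanGenotypeNetworks}}.
#' @param masks a \link[GenomicRanges]{GRanges} of masked intervals or the
#'   path of a BED file.
#' @return The filtered scan table; the number of windows removed is attached
#'   as attribute \code{"n_masked"}.
#' @export
applyMasks <- function(scan, masks) {
  sites <- attr(scan, "sites")
  k <- attr(scan, "k")
  if (is.null(sites) || is.null(k))
    stop("'scan' must come from scanGenotypeNetworks()")
  if (is.character(masks)) masks <- readBedMasks(masks)
  if (length(masks) == 0L || nrow(scan) == 0L) {
    attr(scan, "n_masked") <- 0L
    return(scan)
  }
  siteGr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  maskedSite <- rep(FALSE, nrow(sites))
  maskedSite[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(siteGr, masks))] <- TRUE
  bad <- vapply(scan$first_site,
                function(f) any(maskedSite[f + 0:(k - 1L)]), logical(1))
  out <- scan[!bad, , drop = FALSE]
  attr(out, "sites") <- sites
  attr(out, "k") <- k
  attr(out, "n_masked") <- length(unique(scan$first_site[bad]))
  class(out) <- class(scan)
  out
}

#' Read BED intervals as GRanges
#'
#' Validates the file line by line (reporting the first malformed line) and
#' converts the 0-based half-open BED intervals to 1-based closed ranges.
#'
#' @param path BED file.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
readBedMasks <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (length(f) < 3L || is.na(suppressWarnings(as.numeric(f[2L]))) ||
        is.na(suppressWarnings(as.numeric(f[3L]))) ||
        as.numeric(f[2L]) >= as.numeric(f[3L]))
      stop("malformed BED line ", i, " in ", path, ": ", lines[i])
  }
  if (!any(keep)) return(GRanges())
  f <- do.call(rbind, strsplit(lines[keep], "\t"))
  GRanges(f[, 1L], IRanges(as.numeric(f[, 2L]) + 1L, as.numeric(f[, 3L])))
}

#' Top-scoring regions of a scan
#'
#' Selects the windows whose property value reaches the given upper quantile
#' (ties included), merges overlapping qualifying windows into regions, and
#' ranks regions by their best window value.  Intended to run on a masked
#' scan; candidates are reported for manual inspection, not auto-curated.
#'
#' @param scan a scan table.
#' @param property one of \code{n_vertices}, \code{avg_path_length},
#'   \code{n_components}, \code{avg_degree}, \code{vertices_per_component}.
#' @param quantile upper quantile cutoff (default 0.999).
#' @param population which population's rows to rank (default
#'   \code{"GLOBAL"}).
#' @return Data frame of merged regions: \code{chromosome}, \code{start},
#'   \code{end}, \code{value} (best window), \code{n_windows},
#'   \code{property}, ordered by decreasing value.
#' @export
topRegions <- function(scan, property, quantile = 0.999,
                       population = "GLOBAL") {
  if (!property %in% propertyColumns)
    stop("unknown property '", property, "'; use one of: ",
         paste(propertyColumns, collapse = ", "))
  rows <- scan[scan$population == population, , drop = FALSE]
  vals <- rows[[property]]
  ok <- !is.na(vals)
  thr <- stats::quantile(vals[ok], quantile, names = FALSE, type = 7)
  qual <- rows[ok & vals >= thr, , drop = FALSE]
  if (nrow(qual) == 0L)
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0),
                      n_windows = integer(0), property = character(0)))
  qual <- qual[order(qual$chromosome, qual$start), ]
  regions <- list()
  cur <- qual[1L, ]
  curVal <- cur[[property]]
  curN <- 1L
  flush <- function(cur, curVal, curN)
    data.frame(chromosome = cur$chromosome, start = cur$start, end = cur$end,
               value = curVal, n_windows = curN, property = property,
               stringsAsFactors = FALSE)
  for (i in seq_len(nrow(qual))[-1L]) {
    r <- qual[i, ]
    if (r$chromosome == cur$chromosome && r$start <= cur$end) {
      cur$end <- max(cur$end, r$end)
      curVal <- max(curVal, r[[property]])
      curN <- curN + 1L
    } else {
      regions[[length(regions) + 1L]] <- flush(cur, curVal, curN)
      cur <- r
      curVal <- r[[property]]
      curN <- 1L
    }
  }
  regions[[length(regions) + 1L]] <- flush(cur, curVal, curN)
  out <- do.call(rbind, regions)
  out[order(-out$value), ]
}

#' Window-size sensitivity sweep
#'
#' Recomputes mean network properties for a series of window sizes, each on
#' random haplotype subsamples of a fixed size per population, so that
#' populations of unequal size stay comparable.  Seeded and reproducible.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param kValues window sizes in SNVs (e.g. \code{seq(5, 29, 2)}).
#' @param nResamples random subsamples per window size (default 5).
#' @param resampleSize haplotypes drawn per population.
#' @param seed integer seed.
#' @param step window stride passed to the scan (default 1).
#' @return Long data frame: \code{k}, \code{population}, \code{property},
#'   \code{mean}, \code{sem} over resamples.
#' @export
windowSizeSweep <- function(x, kValues = seq(5L, 29L, by = 2L),
                            nResamples = 5L, resampleSize,
                            seed = 1L, step = 1L) {
  counts <- table(populationLabels(x))
  if (resampleSize > min(counts))
    stop("resampleSize exceeds the smallest population (", min(counts), ")")
  out <- list()
  for (k in kValues) {
    perRep <- lapply(seq_len(nResamples), function(r) {
      sub <- subsampleHaplotypes(x, resampleSize,
                                 seed = seed + 1000L * r + k)
      sc <- scanGenotypeNetworks(sub, k = k, step = step)
      stats::aggregate(sc[propertyColumns], list(population = sc$population),
                       mean, na.rm = TRUE)
    })
    pops <- perRep[[1L]]$population
    for (p in seq_along(pops)) {
      for (prop in propertyColumns) {
        vals <- vapply(perRep, function(d) d[[prop]][p], numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          k = k, population = pops[p], property = prop,
          mean = mean(vals),
          sem = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
                else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
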