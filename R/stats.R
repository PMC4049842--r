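#' Subsampling experiment: network properties versus sample size
#'
#' Quantifies the effect of missing haplotypes: for each sample size, draws
#' random per-population subsamples, scans them, and averages each network
#' property over windows; means and standard errors over replicates form the
#' subsampling curve.  The pooled \code{GLOBAL} rows use all drawn
#' populations together.  The conventional presentation plots the mean with
#' error bars of 6 standard errors of the mean.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param k window size in SNVs (default 11).
#' @param sizes haplotypes per population at each point (descending by
#'   convention); sizes exceeding a population are an error.
#' @param replicates random subsamples per size (default 5).
#' @param seed integer seed.
#' @param step window stride (default \code{k}, i.e. non-overlapping windows,
#'   which keeps the experiment affordable without biasing the means).
#' @param nested use nested subsamples so vertex counts are exactly monotone
#'   in size within a replicate.
#' @return Long data frame: \code{population}, \code{size}, \code{replicate}
#'   averaged out into \code{mean} and \code{sem} per \code{property}.
#' @export
subsamplingExperiment <- function(x, k = 11L,
                                  sizes = c(5000L, 4000L, 3000L, 2000L,
                                            1000L, 500L, 300L, 100L),
                                  replicates = 5L, seed = 1L, step = k,
                                  nested = FALSE) {
  counts <- table(populationLabels(x))
  if (max(sizes) > min(counts))
    stop("largest size (", max(sizes), ") exceeds the smallest population (",
         min(counts), ")")
  perRep <- vector("list", 0L)
  for (r in seq_len(replicates)) {
    for (s in sizes) {
      sub <- subsampleHaplotypes(x, s, seed = seed + 7919L * r,
                                 nested = nested)
      sc <- scanGenotypeNetworks(sub, k = k, step = step)
      agg <- stats::aggregate(sc[propertyColumns],
                              list(population = sc$population), mean,
                              na.rm = TRUE)
      agg$size <- s
      agg$replicate <- r
      perRep[[length(perRep) + 1L]] <- agg
    }
  }
  all <- do.call(rbind, perRep)
  out <- list()
  for (p in unique(all$population)) {
    for (s in sizes) {
      rows <- all[all$population == p & all$size == s, ]
      for (prop in propertyColumns) {
        v <- rows[[prop]]
        out[[length(out) + 1L]] <- data.frame(
          population = p, size = s, property = prop, mean = mean(v),
          sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
          replicates = length(v), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Pairwise correlations between network properties and covariables
#'
#' Pearson correlations over windows between the four network properties and,
#' when present, the window covariables (span in bp, recombination distance in
#' cM).  Rows with an undefined average path length are dropped pairwise.  The
#' vertex count may be log-transformed, which tightens its relationship with
#' the average degree.
#'
#' @param scan a scan table.
#' @param population rows to use (default \code{"GLOBAL"}).
#' @param covariables include \code{span_bp} and \code{recomb_cM} (if
#'   available) alongside the properties.
#' @param logVertices use \code{log10(n_vertices)}.
#' @return List with matrices \code{r} (coefficients; \code{NA} for constant
#'   columns), \code{p} (correlation-test p-values) and \code{n} (pairwise
#'   complete observations).
#' @export
correlateProperties <- function(scan, population = "GLOBAL",
                                covariables = TRUE, logVertices = FALSE) {
  rows <- scan[scan$population == population, , drop = FALSE]
  if (nrow(rows) < 3L) stop("need at least 3 windows")
  cols <- c("n_vertices", "avg_path_length", "n_components", "avg_degree")
  m <- rows[cols]
  if (logVertices) {
    m$n_vertices <- log10(m$n_vertices)
    names(m)[1L] <- "log10_n_vertices"
  }
  if (covariables) {
    cov <- rows[c("span_bp", "recomb_cM")]
    cov <- cov[vapply(cov, function(v) !all(is.na(v)), logical(1))]
    m <- cbind(cov, m)
  }
  m <- as.matrix(m)
  nv <- ncol(m)
  r <- p <- n <- matrix(NA_real_, nv, nv, dimnames = list(colnames(m),
                                                          colnames(m)))
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    ok <- stats::complete.cases(m[, c(i, j)])
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    xi <- m[ok, i]; xj <- m[ok, j]
    if (sum(ok) < 3L || stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    ct <- stats::cor.test(xi, xj, method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}

#' Analysis of covariance across annotation classes
#'
#' Compares network properties between windows classified as \code{coding},
#' \code{both} and \code{noncoding} (\code{no_annotation} windows are
#' excluded), adjusting for recombination: windows with more than
#' \code{recombCutoff} cM between their first and last SNV are removed, and
#' each property is modelled as \code{property ~ class + recomb_cM} (no
#' interaction unless requested).  All pairwise class contrasts are tested
#' with a Bonferroni correction, and covariable-adjusted class means are
#' reported with 2 standard errors.
#'
#' @param scan a scan table with \code{recomb_cM} present.
#' @param population rows to analyse (default \code{"GLOBAL"}).
#' @param recombCutoff windows above this recombination distance are dropped
#'   (default 1 cM).
#' @param interaction add a class x recombination interaction term.
#' @return List of data frames: \code{groupTests} (per property: F statistic
#'   and p-value for the class term), \code{contrasts} (per property and class
#'   pair: difference of adjusted means, raw and Bonferroni-corrected
#'   p-values) and \code{adjustedMeans} (per property and class: adjusted mean
#'   and SEM at the mean recombination distance).
#' @export
ancovaAnnotation <- function(scan, population = "GLOBAL", recombCutoff = 1.0,
                             interaction = FALSE) {
  rows <- scan[scan$population == population, , drop = FALSE]
  rows <- rows[!is.na(rows$recomb_cM) & rows$recomb_cM <= recombCutoff, ]
  rows <- rows[rows$annotation_class != "no_annotation", ]
  if (nrow(rows) == 0L)
    stop("no window left after the recombination and annotation filters")
  rows$annotation_class <- factor(rows$annotation_class,
                                  levels = intersect(
                                    c("coding", "both", "noncoding"),
                                    unique(rows$annotation_class)))
  classes <- levels(rows$annotation_class)
  pairs <- if (length(classes) >= 2L) utils::combn(classes, 2L) else
    matrix(character(0), nrow = 2L)
  groupTests <- contrasts <- adjMeans <- list()
  form <- if (interaction) value ~ annotation_class * recomb_cM else
    value ~ annotation_class + recomb_cM
  for (prop in propertyColumns) {
    d <- data.frame(value = rows[[prop]],
                    annotation_class = rows$annotation_class,
                    recomb_cM = rows$recomb_cM)
    d <- d[stats::complete.cases(d), ]
    sizes <- table(d$annotation_class)
    if (length(unique(d$annotation_class[!is.na(d$value)])) < 2L) {
      warning("property ", prop, ": fewer than two classes with data; skipped")
      next
    }
    fit <- stats::lm(form, data = d)
    an <- stats::anova(fit)
    groupTests[[length(groupTests) + 1L]] <- data.frame(
      property = prop, F = an["annotation_class", "F value"],
      p = an["annotation_class", "Pr(>F)"], stringsAsFactors = FALSE)
    # adjusted means at the common mean recombination distance
    newd <- data.frame(annotation_class = factor(classes, levels = classes),
                       recomb_cM = mean(d$recomb_cM))
    pr <- stats::predict(fit, newdata = newd, se.fit = TRUE)
    adjMeans[[length(adjMeans) + 1L]] <- data.frame(
      property = prop, class = classes, adj_mean = as.numeric(pr$fit),
      sem = as.numeric(pr$se.fit), n = as.integer(sizes[classes]),
      stringsAsFactors = FALSE)
    m <- ncol(pairs)
    for (q in seq_len(m)) {
      c1 <- pairs[1L, q]; c2 <- pairs[2L, q]
      if (sizes[c1] < 2L || sizes[c2] < 2L) {
        warning("contrast ", c1, " vs ", c2, " for ", prop,
                " skipped: class with fewer than 2 windows")
        next
      }
      dd <- droplevels(d[d$annotation_class %in% c(c1, c2), ])
      f2 <- stats::lm(form, data = dd)
      co <- summary(f2)$coefficients
      cname <- grep("^annotation_class", rownames(co), value = TRUE)[1L]
      praw <- co[cname, "Pr(>|t|)"]
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        property = prop, class1 = c1, class2 = c2,
        estimate = -co[cname, "Estimate"],
        p_raw = praw, p_bonferroni = min(1, m * praw),
        stringsAsFactors = FALSE)
    }
  }
  list(groupTests = do.call(rbind, groupTests),
       contrasts = do.call(rbind, contrasts),
       adjustedMeans = do.call(rbind, adjMeans))
}

#' Compare network-property distributions between two scenarios
#'
#' Two-sided Wilcoxon rank-sum test per property over window values of two
#' scans (typically a neutral and a selective-sweep simulation, pooled
#' haplotypes).  Ties are handled by midranks with a normal approximation and
#' continuity correction; exact p-values are used for small samples (both
#' groups below 25 windows) without ties.  Quantile-quantile point pairs are
#' returned for plotting.
#'
#' @param scanA,scanB scan tables computed at the same window size
#'   (conventionally A = neutral, B = sweep).
#' @param population rows to compare (default \code{"GLOBAL"}).
#' @param qqProbs probabilities of the qq pairs.
#' @return List with \code{tests} (per property: Wilcoxon W, p-value,
#'   direction as the sign of the median difference B - A, and the two
#'   medians) and \code{qq} (per property: quantiles of A and B).
#' @export
compareScenarios <- function(scanA, scanB, population = "GLOBAL",
                             qqProbs = seq(0.01, 0.99, by = 0.01)) {
  a <- scanA[scanA$population == population, , drop = FALSE]
  b <- scanB[scanB$population == population, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty scan")
  tests <- qq <- list()
  for (prop in propertyColumns) {
    va <- a[[prop]][!is.na(a[[prop]])]
    vb <- b[[prop]][!is.na(b[[prop]])]
    if (length(va) == 0L || length(vb) == 0L) next
    exact <- length(va) < 25L && length(vb) < 25L &&
      !anyDuplicated(c(va, vb))
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = exact,
                                              correct = TRUE))
    tests[[length(tests) + 1L]] <- data.frame(
      property = prop, W = unname(wt$statistic), p = wt$p.value,
      direction = sign(stats::median(vb) - stats::median(va)),
      median_a = stats::median(va), median_b = stats::median(vb),
      stringsAsFactors = FALSE)
    qq[[length(qq) + 1L]] <- data.frame(
      property = prop, prob = qqProbs,
      quantile_a = stats::quantile(va, qqProbs, names = FALSE),
      quantile_b = stats::quantile(vb, qqProbs, names = FALSE),
      stringsAsFactors = FALSE)
  }
  list(tests = do.call(rbind, tests), qq = do.call(rbind, qq))
}
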