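#' Create a simulation configuration
#'
#' Defaults describe the three-population human demography used throughout:
#' an ancestral African-like population (diploid Ne 12500) from which an
#' out-of-Africa branch (bottleneck Ne 1500) splits 3500 generations ago,
#' itself splitting into Europeans and Asians (Ne 7700 each) 2000 generations
#' ago; 5000 haplotypes are sampled per population.  Mutation and
#' recombination rates are 1.5e-8 and 1e-8 per bp per generation over a 500 kb
#' region.  \code{scale} (default 3) rescales sizes/times down and rates up,
#' preserving the population-scaled parameters; the simulated sample is
#' correspondingly cheaper while staying at the stated sample sizes.
#'
#' @param nHaplotypesPerPop haplotypes sampled per population (5000).
#' @param populations population labels.
#' @param neAncestral,neAfrican,neOoaBottleneck,neEuropean,neAsian diploid
#'   effective sizes per epoch.
#' @param neAfricanPresent,neEuropeanPresent,neAsianPresent diploid sizes
#'   after the recent growth epoch.
#' @param growthStartGenerations onset of recent growth, generations before
#'   present (0 disables growth; defaults to 400, roughly the post-agriculture
#'   expansion).  Growth is only applied when it begins after the Eurasian
#'   split, i.e. within the three-population epoch.
#' @param ooaSplitGenerations,eurasianSplitGenerations split times in
#'   generations before present; set both to 0 for a panmictic control.
#' @param burnInFactor ancestral burn-in length in units of the (scaled)
#'   ancestral diploid size (default 10).
#' @param regionLengthBp,mutationRate,recombinationRate region and per-bp
#'   per-generation rates.
#' @param scale rescaling factor (see above).
#' @param sweep empty list for neutral runs, or the output of
#'   \code{\link{sweepParameters}}.
#' @param seed integer seed governing all randomness.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nHaplotypesPerPop = 5000L,
                             populations = c("AFR", "EUR", "ASN"),
                             neAncestral = 12500, neAfrican = 12500,
                             neOoaBottleneck = 1500, neEuropean = 7700,
                             neAsian = 7700,
                             neAfricanPresent = 25000,
                             neEuropeanPresent = 50000,
                             neAsianPresent = 50000,
                             growthStartGenerations = 400,
                             ooaSplitGenerations = 3500,
                             eurasianSplitGenerations = 2000,
                             burnInFactor = 10,
                             regionLengthBp = 5e5,
                             mutationRate = 1.5e-8,
                             recombinationRate = 1e-8,
                             scale = 3,
                             sweep = list(),
                             seed = 1L) {
  new("SimulationConfig",
      nHaplotypesPerPop = as.integer(nHaplotypesPerPop),
      populations = populations,
      neAncestral = neAncestral, neAfrican = neAfrican,
      neOoaBottleneck = neOoaBottleneck, neEuropean = neEuropean,
      neAsian = neAsian,
      neAfricanPresent = neAfricanPresent,
      neEuropeanPresent = neEuropeanPresent,
      neAsianPresent = neAsianPresent,
      growthStartGenerations = growthStartGenerations,
      ooaSplitGenerations = ooaSplitGenerations,
      eurasianSplitGenerations = eurasianSplitGenerations,
      burnInFactor = burnInFactor, regionLengthBp = regionLengthBp,
      mutationRate = mutationRate, recombinationRate = recombinationRate,
      scale = scale, sweep = sweep, seed = as.integer(seed))
}

#' Selective-sweep parameters
#'
#' The sweep conditions a focal allele to reach \code{finalFrequency} within
#' the swept population by \code{endGenerations} before present: the allele is
#' introduced \code{introGenerations} ago, kept segregating (recurrent
#' mutation on loss), and multiplicative selection with coefficient
#' \code{selectionCoefficient} switches on at the latest generation from which
#' the deterministic logistic trajectory still reaches the target, stopping
#' once the frequency attains it.  Runs whose frequency at the sweep end
#' misses \code{finalFrequency +/- tolerance} (or that fix) are retried from
#' the introduction checkpoint up to \code{maxRetries} times before erroring.
#'
#' @param selectionCoefficient selection coefficient s (default 0.015).
#' @param finalFrequency frequency of the selected allele at the end of the
#'   sweep (0.99).
#' @param population population in which selection acts: one of the sampled
#'   populations (default \code{"EUR"}) or \code{"ALL"} for selection in
#'   every population with the target applied to the pooled frequency.
#' @param sweepPosition bp position of the selected site (default: region
#'   midpoint).
#' @param introGenerations introduction time in generations before present
#'   (default: the split time at which the swept population arises, or twice
#'   the out-of-Africa split for \code{"ALL"}).
#' @param endGenerations when the sweep completes, in generations before
#'   present (0 = at sampling time); afterwards the allele drifts neutrally.
#' @param tolerance acceptance band around the final frequency.
#' @param maxRetries bounded retries of the trajectory.
#' @param schedSafety multiplier on the deterministic time-to-target used to
#'   schedule the onset of selection.
#' @return A list suitable for the \code{sweep} slot of
#'   \code{\link{simulationConfig}}.
#' @export
sweepParameters <- function(selectionCoefficient = 0.015,
                            finalFrequency = 0.99,
                            population = "EUR",
                            sweepPosition = NULL,
                            introGenerations = NULL,
                            endGenerations = 0,
                            tolerance = 0.02,
                            maxRetries = 50L,
                            schedSafety = 1.3) {
  list(selectionCoefficient = selectionCoefficient,
       finalFrequency = finalFrequency,
       population = population,
       sweepPosition = sweepPosition,
       introGenerations = introGenerations,
       endGenerations = endGenerations,
       tolerance = tolerance,
       maxRetries = as.integer(maxRetries),
       schedSafety = schedSafety)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      if (length(object@sweep)) "selective sweep" else "neutral", "scenario\n")
  cat("  sample:", paste(object@nHaplotypesPerPop, collapse = "/"),
      "haplotypes from", paste(object@populations, collapse = ", "), "\n")
  cat("  splits:", object@ooaSplitGenerations, "and",
      object@eurasianSplitGenerations, "generations ago; scale",
      object@scale, "\n")
  cat("  region:", object@regionLengthBp, "bp; mu =", object@mutationRate,
      "; r =", object@recombinationRate, "; seed", object@seed, "\n")
})

scaledParams <- function(config) {
  sc <- config@scale
  f <- function(v) max(1L, as.integer(round(v / sc)))
  list(nAnc = f(config@neAncestral), nAfr = f(config@neAfrican),
       nOoa = f(config@neOoaBottleneck), nEur = f(config@neEuropean),
       nAsn = f(config@neAsian),
       nAfrNow = f(config@neAfricanPresent),
       nEurNow = f(config@neEuropeanPresent),
       nAsnNow = f(config@neAsianPresent),
       tGrowth = if (config@growthStartGenerations > 0)
         f(config@growthStartGenerations) else 0L,
       tOoa = if (config@ooaSplitGenerations > 0)
         f(config@ooaSplitGenerations) else 0L,
       tSplit2 = if (config@eurasianSplitGenerations > 0)
         f(config@eurasianSplitGenerations) else 0L,
       mu = config@mutationRate * sc, r = config@recombinationRate * sc)
}

simulateCore <- function(config, mafThreshold, mafMode, sweep) {
  stopifnot(is(config, "SimulationConfig"))
  p <- scaledParams(config)
  L <- config@regionLengthBp
  burn <- as.integer(round(config@burnInFactor * p$nAnc))
  panmictic <- p$tOoa == 0L

  nHap <- config@nHaplotypesPerPop
  growth <- !panmictic && p$tGrowth > 0L && p$tGrowth < p$tSplit2
  if (panmictic) {
    nHap <- nHap[1L]
    capacity <- 2L * p$nAnc
  } else {
    nHap <- rep_len(nHap, 3L)
    capacity <- 2L * (if (growth) c(p$nAfrNow, p$nEurNow, p$nAsnNow)
                      else c(p$nAfr, p$nEur, p$nAsn))
  }
  if (any(nHap > capacity))
    stop("requested sample exceeds the scaled population size; lower 'scale' ",
         "or the sample size")

  # column capacity: equilibrium segregating sites of the pre-growth
  # metapopulation plus headroom for the mutation influx between column
  # reclamations (the simulator reclaims monomorphic columns every 8
  # generations).  During an explosive-growth epoch the influx of doomed
  # young variants exceeds any reasonable capacity; overflow mutations are
  # then dropped and counted (they sit far below the MAF filter).
  thetaL <- 4 * p$nAnc * p$mu * L
  preGrowthGametes <- if (panmictic) 2 * p$nAnc
  else 2 * (p$nAfr + p$nEur + p$nAsn)
  expS <- thetaL * (log(max(sum(nHap), preGrowthGametes)) + 0.6)
  influx <- preGrowthGametes * p$mu * L * 8
  nSitesCols <- as.integer(64 * ceiling((1.4 * expS + 2.5 * influx + 64) / 64))
  if (nSitesCols >= L)
    stop("region too short for the expected number of segregating sites")
  positions <- withSeed(config@seed,
                        as.numeric(sort(sample.int(L, nSitesCols))))

  sweepArgs <- list(sweep = FALSE, pop = -1L, t_intro = 1L, t_end = 0L,
                    sel_s = 0, f_target = 0.5, f_tol = 1, focal = 0L,
                    safety = 1.3, retries = 0L)
  sw <- config@sweep
  if (sweep) {
    if (!length(sw)) stop("config has no sweep block; use sweepParameters()")
    pos0 <- sw$sweepPosition %||% (L / 2)
    swPop <- toupper(sw$population %||% "EUR")
    if (panmictic) swPop <- "ANC"
    popCode <- switch(swPop, ALL = -1L, ANC = 0L, AFR = 1L, EUR = 3L,
                      ASN = 4L, stop("unknown swept population: ", swPop))
    defaultIntro <- switch(swPop,
                           ALL = 2 * config@ooaSplitGenerations,
                           ANC = 2 * config@scale * burn %/% 3,
                           AFR = config@ooaSplitGenerations,
                           config@eurasianSplitGenerations)
    intro <- sw$introGenerations %||% defaultIntro
    tIntro <- as.integer(round(intro / config@scale))
    tEnd <- as.integer(round((sw$endGenerations %||% 0) / config@scale))
    if (tIntro <= 0L || tIntro >= burn + p$tOoa)
      stop("sweep introduction time must fall inside the simulated span")
    if (tEnd >= tIntro)
      stop("sweep end time must be more recent than its introduction")
    sweepArgs <- list(sweep = TRUE, pop = popCode, t_intro = tIntro,
                      t_end = tEnd,
                      sel_s = sw$selectionCoefficient * config@scale,
                      f_target = sw$finalFrequency,
                      f_tol = sw$tolerance %||% 0.02,
                      focal = which.min(abs(positions - pos0)) - 1L,
                      safety = sw$schedSafety %||% 1.3,
                      retries = sw$maxRetries %||% 50L)
  }

  res <- forward_sim_cpp(
    n_dip = c(p$nAnc, p$nAfr, p$nOoa, p$nEur, p$nAsn),
    n_dip_present = c(p$nAfrNow, p$nEurNow, p$nAsnNow),
    t_growth = if (growth) p$tGrowth else 0L,
    burn_gens = burn, t_ooa = p$tOoa, t_split2 = p$tSplit2,
    positions = positions, region_length = L,
    lam_mut = p$mu * L, lam_rec = p$r * L,
    n_hap_sample = as.integer(nHap),
    sweep = sweepArgs$sweep, sweep_pop = sweepArgs$pop,
    t_intro = sweepArgs$t_intro, t_end = sweepArgs$t_end,
    sel_s = sweepArgs$sel_s, f_target = sweepArgs$f_target,
    f_tol = sweepArgs$f_tol, focal_site = sweepArgs$focal,
    sched_safety = sweepArgs$safety, max_retries = sweepArgs$retries,
    seed2 = c(config@seed, 104729L + as.integer(sweep)))

  labels <- if (panmictic) config@populations[1L] else c("AFR", "EUR", "ASN")
  alleles <- matrix(as.integer(res$alleles), nrow = nrow(res$alleles))
  hm <- HaplotypeMatrix(alleles, positions = res$positions,
                        chromosome = "sim1",
                        populations = rep(labels, times = res$pop_sizes),
                        metadata = list(simulation = list(
                          scenario = if (sweep) "sweep" else "neutral",
                          sweptPopulation = if (sweep)
                            (config@sweep$population %||% "EUR") else NA_character_,
                          seed = config@seed,
                          finalFrequency = res$final_freq,
                          focalPosition = if (!is.na(res$focal_col) &&
                                              res$focal_col > 0)
                            res$positions[res$focal_col] else NA_real_,
                          retries = res$retries,
                          reintroductions = res$reintroductions,
                          skippedMutations = res$skipped_mutations,
                          onsetGenerationsBeforePresent =
                            if (is.na(res$onset_tbp)) NA_real_
                            else res$onset_tbp * config@scale)))
  if (mafThreshold > 0) hm <- mafFilter(hm, mafThreshold, mafMode)
  hm
}

#' Simulate a neutral multi-population haplotype sample
#'
#' Forward-in-time Wright-Fisher simulation under the configured demography,
#' followed (by default) by the simulation-data site filter: minor allele
#' frequency at least 0.01 in at least one population.  Identical
#' configuration and seed give byte-identical output.
#'
#' @param config a \linkS4class{SimulationConfig} without a sweep block.
#' @param mafThreshold,mafMode site filter applied to the sample (defaults
#'   0.01, \code{"any_population"}); set \code{mafThreshold = 0} for the raw
#'   sample.
#' @return A \linkS4class{HaplotypeMatrix}; simulation diagnostics are in
#'   \code{metadata()$simulation}.
#' @export
simulateNeutral <- function(config, mafThreshold = 0.01,
                            mafMode = "any_population") {
  simulateCore(config, mafThreshold, mafMode, sweep = FALSE)
}

#' Simulate a selective sweep
#'
#' As \code{\link{simulateNeutral}}, plus a selective sweep conditioned so the
#' selected allele reaches its target frequency (default 0.99, selection
#' coefficient 0.015) in the pooled sample at sampling time.  Trajectories
#' that miss the target band are retried from the introduction checkpoint; an
#' error reports the retry count if the bound is exhausted.
#'
#' @inheritParams simulateNeutral
#' @param config a \linkS4class{SimulationConfig} whose \code{sweep} slot was
#'   filled with \code{\link{sweepParameters}}.
#' @return A \linkS4class{HaplotypeMatrix}; \code{metadata()$simulation}
#'   records the realised final frequency, the focal position, retries and
#'   re-introductions.
#' @export
simulateSweep <- function(config, mafThreshold = 0.01,
                          mafMode = "any_population") {
  simulateCore(config, mafThreshold, mafMode, sweep = TRUE)
}
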