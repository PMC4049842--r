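# forward Wright-Fisher simulator: determinism, coalescent sanity, sweep
# conditioning, subsampling

test_that("identical configuration and seed give byte-identical samples", {
  cfg <- smallNeutralConfig(seed = 21L)
  a <- simulateNeutral(cfg)
  b <- simulateNeutral(cfg)
  expect_identical(alleleMatrix(a), alleleMatrix(b))
  expect_identical(sitePositions(a), sitePositions(b))
  c <- simulateNeutral(smallNeutralConfig(seed = 22L))
  expect_false(identical(alleleMatrix(a), alleleMatrix(c)))
})

test_that("panmictic neutral sample matches coalescent expectations", {
  # theta = 4*N*mu*L = 5; n = 100 haplotypes
  theta <- 5
  n <- 100L
  an <- sum(1 / seq_len(n - 1L))
  bn <- sum(1 / seq_len(n - 1L)^2)
  reps <- 200L
  S <- numeric(reps)
  piv <- numeric(reps)
  for (i in seq_len(reps)) {
    hm <- simulateNeutral(
      simulationConfig(nHaplotypesPerPop = n, neAncestral = 500,
                       ooaSplitGenerations = 0, eurasianSplitGenerations = 0,
                       growthStartGenerations = 0, regionLengthBp = 1e5,
                       mutationRate = 2.5e-8, burnInFactor = 16,
                       scale = 1, seed = 3000L + i),
      mafThreshold = 0)
    expect_equal(metadata(hm)$simulation$skippedMutations, 0)
    S[i] <- nSites(hm)
    f <- colSums(alleleMatrix(hm)) / n
    piv[i] <- sum(2 * f * (1 - f)) * n / (n - 1L)
  }
  # Watterson: E[S] = theta * a_{n-1}; SE over replicates from Var(S)
  expS <- theta * an
  seS <- sqrt(an * theta + bn * theta^2) / sqrt(reps)
  expect_lt(abs(mean(S) - expS), 3 * seS)
  # pairwise diversity: E[pi] = theta
  varPi <- (n + 1) * theta / (3 * (n - 1)) +
    2 * (n^2 + n + 3) * theta^2 / (9 * n * (n - 1))
  expect_lt(abs(mean(piv) - theta), 3 * sqrt(varPi / reps))
})

test_that("out-of-Africa bottleneck orders haplotype diversity by population", {
  # AFR keeps more distinct short haplotypes, averaged over windows and
  # replicates, than the bottlenecked branches
  afr <- eur <- numeric(10)
  for (i in seq_along(afr)) {
    hm <- simulateNeutral(
      simulationConfig(nHaplotypesPerPop = 80L, neAncestral = 500,
                       neAfrican = 500, neOoaBottleneck = 50,
                       neEuropean = 300, neAsian = 300,
                       growthStartGenerations = 0,
                       ooaSplitGenerations = 400,
                       eurasianSplitGenerations = 100, burnInFactor = 8,
                       regionLengthBp = 8e4, scale = 1, seed = 400L + i))
    sc <- scanGenotypeNetworks(hm, k = 5L, step = 5L)
    m <- function(p) mean(sc$n_vertices[sc$population == p])
    afr[i] <- m("AFR")
    eur[i] <- mean(c(m("EUR"), m("ASN")))
  }
  expect_gt(mean(afr), mean(eur))
})

test_that("sweep conditioning reaches the target frequency", {
  # sweep ending at sampling time: sample frequency of the focal allele ~ 0.99
  cfg <- simulationConfig(
    nHaplotypesPerPop = 200L, neAncestral = 500, neAfrican = 500,
    neOoaBottleneck = 120, neEuropean = 350, neAsian = 350,
    growthStartGenerations = 0, ooaSplitGenerations = 300,
    eurasianSplitGenerations = 150, burnInFactor = 8,
    regionLengthBp = 1e5, scale = 1, seed = 99L,
    sweep = sweepParameters(population = "ALL", endGenerations = 0,
                            introGenerations = 900))
  hm <- simulateSweep(cfg, mafThreshold = 0)
  md <- metadata(hm)$simulation
  expect_equal(md$scenario, "sweep")
  expect_lt(abs(md$finalFrequency - 0.99), 0.02 + 1e-9)
  # frequency in the sampled haplotypes agrees within sampling error
  focal <- which(sitePositions(hm) == md$focalPosition)
  expect_length(focal, 1L)
  fSample <- mean(alleleMatrix(hm)[, focal])
  expect_lt(abs(fSample - 0.99), 3 * sqrt(0.99 * 0.01 / nHaplotypes(hm)) + 0.02)
})

test_that("a selectionless sweep run stays statistically neutral", {
  # s = 0 with an unconstrained final frequency only conditions the focal
  # allele on segregating; diversity matches plain neutral runs
  piOf <- function(hm) {
    f <- colMeans(alleleMatrix(hm))
    n <- nHaplotypes(hm)
    sum(2 * f * (1 - f)) * n / (n - 1L)
  }
  piN <- piS <- numeric(12)
  for (i in seq_along(piN)) {
    base <- panmicticConfig(seed = 600L + i, nHap = 80L, ne = 250,
                            regionLength = 8e4)
    piN[i] <- piOf(simulateNeutral(base, mafThreshold = 0))
    swCfg <- simulationConfig(
      nHaplotypesPerPop = 80L, neAncestral = 250, ooaSplitGenerations = 0,
      eurasianSplitGenerations = 0, growthStartGenerations = 0,
      regionLengthBp = 8e4, scale = 1, seed = 600L + i,
      sweep = sweepParameters(selectionCoefficient = 0, finalFrequency = 0.5,
                              tolerance = 1, endGenerations = 0,
                              introGenerations = 800))
    piS[i] <- piOf(simulateSweep(swCfg, mafThreshold = 0))
  }
  expect_gt(stats::wilcox.test(piN, piS)$p.value, 0.005)
})

test_that("unattainable sweep trajectories error with the retry count", {
  cfg <- simulationConfig(
    nHaplotypesPerPop = 40L, neAncestral = 150, ooaSplitGenerations = 0,
    eurasianSplitGenerations = 0, growthStartGenerations = 0,
    regionLengthBp = 5e4, scale = 1, seed = 5L,
    sweep = sweepParameters(selectionCoefficient = 0, finalFrequency = 0.999,
                            tolerance = 0.0005, endGenerations = 0,
                            introGenerations = 200, maxRetries = 3L))
  expect_error(simulateSweep(cfg), "retries")
})

test_that("simulated output passes the any-population MAF filter by default", {
  cfg <- smallNeutralConfig(seed = 31L, nHap = 100L)
  raw <- simulateNeutral(cfg, mafThreshold = 0)
  filt <- simulateNeutral(cfg)
  expect_lte(nSites(filt), nSites(raw))
  pops <- populationLabels(filt)
  a <- alleleMatrix(filt)
  mafs <- sapply(split(seq_along(pops), pops), function(idx) {
    f <- colMeans(a[idx, , drop = FALSE])
    pmin(f, 1 - f)
  })
  expect_true(all(apply(mafs, 1L, max) >= 0.01))
})

test_that("subsampling is stratified, nested when asked, and vertex-nesting", {
  hm <- simulateNeutral(smallNeutralConfig(seed = 51L, nHap = 60L))
  sub <- subsampleHaplotypes(hm, 20L, seed = 9L)
  expect_equal(unname(table(populationLabels(sub))), rep(20L, 3L),
               ignore_attr = TRUE)
  # identity when n equals every population
  all3 <- subsampleHaplotypes(hm, 60L, seed = 9L)
  expect_identical(alleleMatrix(all3), alleleMatrix(hm))
  # nested mode: the size-10 draw is inside the size-20 draw
  s10 <- subsampleHaplotypes(hm, 10L, seed = 9L, nested = TRUE)
  s20 <- subsampleHaplotypes(hm, 20L, seed = 9L, nested = TRUE)
  key <- function(x) apply(alleleMatrix(x), 1L, paste, collapse = "")
  expect_true(all(rownames(colData(s10)) %in% rownames(colData(s20))))
  # vertex nesting: windows on a subsample never gain vertices
  k <- min(8L, nSites(hm))
  full <- buildNetwork(genotypeStrings(hm, seq_len(k)))
  part <- buildNetwork(genotypeStrings(s20, seq_len(k)))
  expect_lte(nVertices(part), nVertices(full))
  expect_true(all(names(part@nodeCounts) %in% names(full@nodeCounts)))
  expect_error(subsampleHaplotypes(hm, 1000L, seed = 1L), "exceeds")
})
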