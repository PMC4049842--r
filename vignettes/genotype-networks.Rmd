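---
title: "Genotype networks for population-genetic genome scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype networks for population-genetic genome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genonet)
```

## The method

A *genotype network* is a graph whose nodes are the distinct haplotypes
observed in a sample over a short stretch of biallelic SNVs, encoded as binary
strings (0 = reference allele, 1 = alternative allele), with an edge joining
two nodes whenever their strings differ at exactly one site — one mutational
step.  The full genotype space over `k` sites is the `k`-dimensional
hypercube; a population occupies a small region of it, and the shape of that
region is informative about the population's history.

Four statistics summarise each network:

* **number of vertices** — the count of distinct haplotypes (Nei's number of
  distinct haplotypes); how much of genotype space the sample occupies;
* **average path length** — the mean shortest-path length over connected node
  pairs; how far the network extends, i.e. how heterogeneous the sample is;
* **number of components** — maximal connected subgraphs (isolated nodes
  count); how fragmented the occupied region is;
* **average degree** — mean neighbour count over all nodes (isolated nodes
  contribute zero, so it equals 2E/V); how stable the network is to point
  mutations, since a random point mutation of a sampled haplotype lands on a
  neighbour in genotype space, and a high degree means that neighbour is
  likely already part of the network.

The package computes these in sliding windows of a fixed number of SNVs
(default 11, stride 1) along a chromosome, separately per population and for
all haplotypes pooled (`GLOBAL`), from phased VCF input, ms-format blocks, or
its own simulator.  Windows are indexed by SNV count rather than base pairs so
that networks of different genomic regions are comparable; the base-pair span
and the genetic-map distance between the first and last SNV travel along as
covariables, because both correlate with the network statistics.

### Conventions and edge cases

* Sites must be biallelic SNVs; multiallelic records, indels, and sites with
  unphased or missing genotypes are dropped (and counted) at load time.
* The minor-allele-frequency filter has two explicit modes: `global` (MAF over
  all haplotypes pooled) and `any_population` (keep a site whose MAF clears
  the threshold in at least one population, i.e. drop sites rare everywhere).
  The mode is a required argument: the two rules answer different questions
  and silently defaulting one would be misleading.
* Average path length is computed over connected pairs only, the convention of
  the igraph library; a network with no edges has an undefined average path
  length, reported as `NA` and omitted from output tracks rather than coded
  as 0.
* Haplotype multiplicities are recorded per node but deliberately do not
  weight any property: the statistics describe the occupied region of genotype
  space, not the frequency distribution on it.
* Coordinates are 1-based closed internally (region notation
  `chr6:32507854-32508257`); emitted bedGraph/BED files are 0-based half-open
  per those formats.  Window spans are `[first SNV position, last SNV
  position]`.
* Edge construction generates each node's `k` single-bit flips and looks them
  up in a hash index — O(V·k) — rather than comparing all node pairs; the
  all-pairs O(V²k) constructor is kept as an independent oracle for testing.

## The simulator

`simulateNeutral()` and `simulateSweep()` generate phased multi-population
haplotype samples with a forward-in-time Wright–Fisher model written for this
package (bit-packed haplotypes, compiled core).  Forward simulation was chosen
over a coalescent because the package needs a selective sweep embedded in a
multi-population demography under full user control of the conditioning; the
cost is managed by the standard rescaling trick (below).

The default demography is a three-population human-like history, with all
parameters exposed in `simulationConfig()`:

| parameter | default | meaning |
|---|---|---|
| `neAncestral`, `neAfrican` | 12500 | diploid Ne of the ancestral/African lineage |
| `neOoaBottleneck` | 1500 | Ne of the out-of-Africa branch between splits |
| `neEuropean`, `neAsian` | 7700 | Ne after the European–Asian split |
| `ooaSplitGenerations` | 3500 | out-of-Africa split, generations ago |
| `eurasianSplitGenerations` | 2000 | European–Asian split, generations ago |
| `neAfricanPresent` / `neEuropeanPresent` / `neAsianPresent` | 25000 / 50000 / 50000 | sizes after recent growth |
| `growthStartGenerations` | 400 | onset of recent growth |
| `regionLengthBp` | 5e5 | simulated region |
| `mutationRate`, `recombinationRate` | 1.5e-8, 1e-8 | per bp per generation |
| `nHaplotypesPerPop` | 5000 | sampled haplotypes per population |

The two split times are the published values of the calibrated human
demographic model this history follows; the epoch sizes and the recent-growth
block are this package's own defaults in the spirit of that model (constant
sizes within epochs, a severe out-of-Africa bottleneck, and explosive recent
growth).  Growth matters more than it may seem: very rare haplotype classes —
young mutations and fresh recombinants — only exist at realistic sample sizes
if the present-day population is much larger than the long-term effective
size, and those rare classes are precisely what large-sample genotype networks
see as extra vertices.

**Rescaling.**  `scale` (default 3) divides population sizes and epoch times
and multiplies the mutation rate, recombination rate and selection coefficient,
preserving the population-scaled parameters θ = 4Nμ, ρ = 4Nr and 2Ns.  This is
the standard forward-simulation rescaling; its cost is coarser frequency
granularity (no lineage rarer than 1/2N·scale exists) and slightly more
drift-dominated trajectories.  The default keeps the scaled present-day
populations several times larger than the 5000-haplotype samples.

**Finite-site bookkeeping.**  Haplotypes live on a fixed pool of site columns;
monomorphic columns are reclaimed every 8 generations and re-used for new
mutations, which keeps the model effectively infinite-sites as long as free
columns remain.  The pool is sized for the equilibrium segregating-site count
plus the mutation influx of one reclamation interval.  During an
explosive-growth epoch the influx of doomed young variants exceeds any
reasonable pool; overflow mutations are then dropped and counted
(`metadata()$simulation$skippedMutations`).  The affected variants are the
youngest and rarest — far below the 1% MAF filter every analysis here applies —
but the raw (unfiltered) rare site-frequency spectrum of a growth-epoch sample
is thinned, and analyses of singleton counts should not use growth epochs with
this simulator.

**Sweep conditioning.**  The sweep follows the conventions of
coalescent/forward sweep simulators: the selected allele is introduced as a
single copy in the swept population (`population`, default `"EUR"`;
`"ALL"` selects in every population against the pooled frequency) at
`introGenerations`, is conditioned on segregating — a lost allele is
re-introduced, i.e. recurrent mutation at the focal site — and multiplicative
selection (fitness 1, 1+s, (1+s)² with s = 0.015 by default) switches on at
the latest generation from which the deterministic logistic trajectory still
reaches `finalFrequency` (default 0.99) by `endGenerations` before present;
selection stops once the target is reached and the allele drifts neutrally
afterwards.  Runs whose frequency at the sweep's end misses the target band
are retried from a checkpoint taken at the introduction (bounded by
`maxRetries`; the error reports the count).  The realised frequency, onset
generation, retries and re-introductions are recorded in
`metadata()$simulation`.

The "final frequency" is thus a property of the sweep's end, not necessarily
of the sampling time, matching how sweep simulators parameterise partial
sweeps; `endGenerations = 0` makes the two coincide.

## What the simulations can and cannot show

The simulator emulates: three-population structure with realistic splits and
bottleneck, per-population sample sizes up to the configured population sizes,
uniform mutation and crossover recombination, MAF-filtered phased output
identical in shape to VCF-loaded data, and sweeps with controlled end
frequency.  It does not emulate: recombination-map heterogeneity (hotspots),
gene conversion, migration/admixture after the splits, variable coverage or
phasing error, or functional annotation structure (annotation classes on
simulated sites must be injected by the user).  Tests passing on simulated
data therefore validate the machinery and the qualitative demographic
signatures (e.g. African samples carrying more distinct haplotypes than
bottlenecked populations; vertex counts growing with sample size), not any
claim about a particular real dataset.

A note on neutral-versus-sweep comparisons: in these simulations a completed
selective sweep acting on one population increases the pooled number of
vertices and the average path length of windows around the swept site — the
swept population contributes novel recombinant mosaics of the core haplotype
while the unswept populations keep the SNV panel above the MAF filter.  That
effect, however, requires fine frequency granularity: it emerges at the
default `scale = 3` with the full 15000-haplotype pooled sample, where rare
recombinant classes are individually visible, and it inverts at coarser
rescalings or small samples, where the sweep's loss of diversity dominates
every property.  The average degree and the number of components respond
weakly in either regime.  Other simulation engines, whose full parameter
files (migration models, sweep end times, region lengths) are not published
in reusable form, have been reported to show all four properties responding
positively (components negatively); this package treats "sweep versus
neutral" as an empirical comparison for the user to run at adequate scale
(`compareScenarios()`), and documents the granularity caveat here rather than
presenting the four-way signature as a guaranteed property of sweeps.

## Statistical analyses

* `subsamplingExperiment()` draws per-population subsamples of decreasing
  size (default 5000…100, 5 replicates) and averages each property over
  windows, reproducing the sample-size sensitivity analysis; plots
  conventionally show 6 standard errors of the mean.  Non-overlapping windows
  (stride = window size) are used by default: means are unbiased either way
  and the experiment is an order of magnitude cheaper.
* `correlateProperties()` computes pairwise Pearson correlations over windows
  between properties and covariables (bp span, recombination distance), with
  an optional log scale for the vertex count.
* `ancovaAnnotation()` compares annotation classes (coding / both /
  noncoding; windows whose SNVs carry no annotation are excluded) adjusting
  for recombination: windows with more than 1 cM between first and last SNV
  are removed, and each property is fitted as `property ~ class + recomb_cM`,
  an ordinary linear model without interaction (the interaction term is
  exposed as an option but off by default — with it, "the class effect" is no
  longer a single quantity).  Pairwise class contrasts are
  Bonferroni-corrected; adjusted class means are reported with 2 standard
  errors, evaluated at the common mean recombination distance.
* `compareScenarios()` runs two-sided Wilcoxon rank-sum tests per property
  over window values of two scans and emits quantile–quantile pairs.  Exact
  p-values are used only for small tie-free samples (both sides < 25); midranks
  with normal approximation and continuity correction otherwise.

## Numerical and design choices

* Window stride defaults to 1 SNV (maximal overlap).  Any coarser stride is a
  subsample of the stride-1 scan; experiments that average over windows use
  stride = k for cost.
* The top-region report applies an upper-quantile cutoff (default 0.999) with
  ties included, merges overlapping qualifying windows and ranks by the best
  window; it is a candidate list for manual inspection, not an automated
  curation.
* Masks (assembly gaps, centromeres, telomeres) are user-supplied BED files;
  nothing genome-specific is hard-coded.
* Genetic-map lookups interpolate linearly and extrapolate flat beyond the map
  (counted and messaged).
* Subsampling can run in nested mode, where draws of increasing size are
  nested so vertex counts are exactly monotone per replicate, not only in
  expectation.
* Seeds: every stochastic entry point takes an explicit integer seed, restores
  the caller's RNG state, and derives the compiled simulator's stream from the
  same seed, so identical configurations are byte-identical across runs.

## Problem sizes used in the bundled checks

The test-suite and acceptance checks run reduced problem sizes chosen so the
whole suite completes on a laptop-class single core: coalescent sanity checks
use panmictic populations of a few hundred with ~100-haplotype samples over
50–100 kb; scenario comparisons use the default demography at `scale` 15–25
with a few hundred haplotypes per population over 200 kb and dozens of
replicate pairs; the subsampling curve runs one default-scale dataset
(5000 haplotypes per population, 500 kb).  These are the package's standard
desk-scale settings; all of them are plain `simulationConfig()` calls that
users can scale up.

## Limitations

* The forward simulator is not a drop-in for a calibrated coalescent: absolute
  levels of diversity match coalescent expectations (tested), but
  finest-resolution rare variation during growth epochs is thinned by design.
* Network properties depend on sample size (that is the point of the
  subsampling analysis); comparing scans of different sample sizes is
  meaningless without subsampling to a common size.
* ANCOVA assumes an additive covariable effect on each property; properties
  with strongly non-linear recombination response should be compared within
  recombination strata instead.
* The scan holds the SNV-count window fixed; regions whose filtered SNV
  density differs wildly will have windows of very different physical size,
  which is why span and recombination distance are carried as covariables.
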