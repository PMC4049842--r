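# sliding-window scan, annotation classes, masks, top regions, tracks

test_that("window enumeration counts and spans are exact", {
  set.seed(1)
  hm <- hmFromStrings(randomGenotypes(8L, 25L), positions = seq_len(25L) * 100L)
  w1 <- iterWindows(hm, k = 11L, step = 1L)
  expect_equal(nrow(w1), 15L)  # 25 - 11 + 1
  w2 <- iterWindows(hm, k = 11L, step = 11L)
  expect_equal(nrow(w2), 2L)   # trailing partial window dropped
  expect_equal(w2$first_site, c(1L, 12L))
  expect_equal(w2$start, c(100L, 1200L))
  expect_equal(w2$end, c(1100L, 2200L))
  expect_equal(w2$span_bp, c(1000L, 1000L))
  hm10 <- hmFromStrings(c("0000000000", "1111111111"),
                        positions = seq_len(10L) * 10L)
  expect_warning(w0 <- iterWindows(hm10, k = 11L), "zero windows")
  expect_equal(nrow(w0), 0L)
})

test_that("windows never span chromosomes", {
  a <- matrix(rep(c(0L, 1L), each = 12L), nrow = 2L, byrow = TRUE)
  hm <- HaplotypeMatrix(a, positions = rep(seq_len(6L) * 50L, 2L),
                        chromosome = rep(c("chr1", "chr2"), each = 6L))
  w <- iterWindows(hm, k = 4L, step = 1L)
  expect_equal(nrow(w), 6L)  # 3 per chromosome
  expect_true(all(table(w$chromosome) == 3L))
})

test_that("scan emits one row per window and population plus GLOBAL", {
  set.seed(2)
  strings <- randomGenotypes(30L, 20L)
  hm <- hmFromStrings(strings, populations = rep(c("A", "B"), 15L),
                      positions = seq_len(20L) * 25L)
  sc <- scanGenotypeNetworks(hm, k = 6L, step = 7L)
  wins <- iterWindows(hm, k = 6L, step = 7L)
  expect_equal(nrow(sc), nrow(wins) * 3L)
  expect_setequal(unique(sc$population), c("A", "B", "GLOBAL"))
  # GLOBAL vertex set contains each population's for every window
  for (f in unique(sc$first_site)) {
    g <- sc[sc$first_site == f & sc$population == "GLOBAL", "n_vertices"]
    for (p in c("A", "B"))
      expect_gte(g, sc[sc$first_site == f & sc$population == p, "n_vertices"])
  }
})

test_that("identical haplotypes give single-vertex windows everywhere", {
  hm <- hmFromStrings(rep("001100110011", 40L),
                      populations = rep(c("A", "B"), 20L),
                      positions = seq_len(12L) * 10L)
  sc <- scanGenotypeNetworks(hm, k = 4L, step = 4L)
  expect_true(all(sc$n_vertices == 1L))
  expect_true(all(sc$avg_degree == 0))
  expect_true(all(is.na(sc$avg_path_length)))
})

test_that("window annotation classes follow the coding/noncoding rule", {
  expect_equal(classifyWindowAnnotation(c("coding", "none", "coding")),
               "coding")
  expect_equal(classifyWindowAnnotation(c("coding", "noncoding")), "both")
  expect_equal(classifyWindowAnnotation(c("none", "noncoding")), "noncoding")
  expect_equal(classifyWindowAnnotation(rep("none", 11L)), "no_annotation")
})

test_that("genetic-map interpolation attaches recombination distances", {
  hm <- hmFromStrings(c("010101", "101010", "011011", "110110"),
                      positions = c(100L, 200L, 300L, 400L, 500L, 600L))
  map <- data.frame(chrom = "chr1", pos = c(100L, 600L), cM = c(0, 1))
  sc <- scanGenotypeNetworks(hm, k = 3L, step = 3L, geneticMap = map)
  w1 <- sc[sc$first_site == 1L, ][1L, ]
  expect_equal(w1$recomb_cM, (300 - 100) / 500, tolerance = 1e-12)
  # positions beyond the map take the nearest endpoint (flat extrapolation)
  map2 <- data.frame(chrom = "chr1", pos = c(150L, 350L), cM = c(0, 1))
  expect_message(
    cm <- interpolateGeneticMap(map2, "chr1", c(100L, 350L, 500L)),
    "outside the genetic map")
  expect_equal(as.numeric(cm), c(0, 1, 1))
  expect_equal(attr(cm, "n_extrapolated"), 2L)
})

test_that("masks remove exactly the windows touching masked SNVs", {
  hm <- hmFromStrings(randomGenotypes(10L, 8L),
                      positions = c(100L, 120L, 150L, 160L, 200L, 250L,
                                    300L, 350L))
  sc <- scanGenotypeNetworks(hm, k = 3L, step = 1L)
  # BED [150,160) covers only the SNV at position 151..160? 0-based half-open:
  # interval (150,160] in 1-based -> hits the site at 160 but not 150
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151L, 160L))
  out <- applyMasks(sc, mask)
  touched <- vapply(unique(sc$first_site), function(f)
    any(sitePositions(hm)[f + 0:2] == 160L), logical(1))
  expect_equal(attr(out, "n_masked"), sum(touched))
  expect_false(any(out$first_site %in% unique(sc$first_site)[touched]))
  # empty mask list is the identity
  same <- applyMasks(sc, GenomicRanges::GRanges())
  expect_equal(nrow(same), nrow(sc))
  # masks are monotone: a larger mask never retains more windows
  bigger <- applyMasks(sc, GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(100L, 200L)))
  expect_lte(nrow(bigger), nrow(out))
})

test_that("BED masks parse 0-based half-open and report malformed lines", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t150\t160"), bed)
  gr <- readBedMasks(bed)
  expect_equal(GenomicRanges::start(gr), 151L)
  expect_equal(GenomicRanges::end(gr), 160L)
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\toops"), bad)
  expect_error(readBedMasks(bad), "line 2")
})

test_that("top regions apply the quantile with ties and merge overlaps", {
  sc <- data.frame(chromosome = "chr1",
                   first_site = 1:100, start = (1:100) * 10,
                   end = (1:100) * 10 + 25, span_bp = 25,
                   recomb_cM = NA_real_, annotation_class = "none",
                   population = "GLOBAL",
                   n_vertices = c(rep(1, 90), rep(9, 5), rep(10, 5)),
                   avg_path_length = 1, n_components = 1L, avg_degree = 1,
                   vertices_per_component = 1)
  top <- topRegions(sc, "n_vertices", quantile = 0.95)
  # >= 5 qualifying windows, ties included; overlapping ones merge
  expect_gte(sum(top$n_windows), 5L)
  expect_true(all(top$value >= 9))
  expect_error(topRegions(sc, "banana"), "unknown property")
  # two overlapping qualifying windows merge into one region
  sc2 <- sc[1:2, ]
  sc2$n_vertices <- c(5, 6)
  sc2$end <- c(40, 60)  # starts 10, 20 overlap
  top2 <- topRegions(sc2, "n_vertices", quantile = 0)
  expect_equal(nrow(top2), 1L)
  expect_equal(top2$n_windows, 2L)
  expect_equal(top2$value, 6)
})

test_that("bedGraph tracks round-trip scan values exactly", {
  set.seed(9)
  hm <- hmFromStrings(randomGenotypes(24L, 12L),
                      populations = rep(c("A", "B"), 12L),
                      positions = sort(sample(1e4, 12L)))
  sc <- scanGenotypeNetworks(hm, k = 5L, step = 2L)
  out <- tempfile()
  files <- writeTracks(sc, out)
  f <- file.path(out, "avg_path_length.GLOBAL.bedGraph")
  expect_true(file.exists(f))
  got <- read.table(f, sep = "\t")
  rows <- sc[sc$population == "GLOBAL", ]
  ok <- !is.na(rows$avg_path_length)
  expect_equal(nrow(got), sum(ok))          # undefined APL rows omitted
  expect_identical(got$V4, rows$avg_path_length[ok])  # exact round-trip
  expect_equal(got$V2, rows$start[ok] - 1L) # 0-based start conversion
  expect_equal(got$V3, rows$end[ok])
  # 4 property tracks x 3 populations + vpc track x 3 + 5 top-region BEDs
  expect_true(file.exists(file.path(out, "n_vertices.A.bedGraph")))
  # independent parser agrees on an arbitrary track
  gr <- rtracklayer::import(f, format = "bedGraph")
  expect_equal(gr$score, rows$avg_path_length[ok])
})

test_that("window-size sweep is seeded and degenerates to the direct scan", {
  set.seed(4)
  hm <- hmFromStrings(randomGenotypes(20L, 18L),
                      populations = rep(c("A", "B"), 10L),
                      positions = seq_len(18L) * 11L)
  t1 <- windowSizeSweep(hm, kValues = c(5L, 7L), nResamples = 2L,
                        resampleSize = 8L, seed = 3L)
  t2 <- windowSizeSweep(hm, kValues = c(5L, 7L), nResamples = 2L,
                        resampleSize = 8L, seed = 3L)
  expect_identical(t1, t2)  # determinism
  expect_error(windowSizeSweep(hm, kValues = 5L, nResamples = 1L,
                               resampleSize = 11L), "exceeds")
  # one resample of every haplotype equals the direct scan means
  t3 <- windowSizeSweep(hm, kValues = 5L, nResamples = 1L,
                        resampleSize = 10L, seed = 1L)
  sc <- scanGenotypeNetworks(hm, k = 5L)
  direct <- mean(sc$n_vertices[sc$population == "GLOBAL"])
  expect_equal(t3$mean[t3$population == "GLOBAL" &
                         t3$property == "n_vertices"], direct)
})
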