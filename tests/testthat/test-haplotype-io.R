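# VCF / ms-format loading, binary encoding, and the site filters

fixtures <- makeFixtures(file.path(tempdir(), "genonet-fixtures"), seed = 1L)

test_that("a clean phased VCF round-trips through write and load", {
  hm <- hmFromStrings(c("00000", "00001", "01001", "00011", "01100", "00101",
                        "00000", "00001", "10000", "00000"),
                      populations = rep(c("AFR", "EUR"), each = 5L))
  f <- tempfile(fileext = ".vcf")
  writePhasedVcf(hm, f)
  back <- loadPhasedVcf(f, mafThreshold = 0)
  expect_identical(alleleMatrix(back), alleleMatrix(hm))
  expect_identical(sitePositions(back), sitePositions(hm))
  # the loaded strings match hand-encoded expectations
  expect_identical(genotypeStrings(back)[1:2], c("00000", "00001"))
})

test_that("loader drops triallelic, non-SNV, unphased and missing sites with counts", {
  hm <- loadPhasedVcf(fixtures[["filters_vcf"]], mafThreshold = 0)
  # 7 records: clean1, triallelic, indel, unphased, missing, rare, clean2
  expect_equal(nSites(hm), 3L)  # clean1, rare, clean2 survive
  fc <- metadata(hm)$filterCounts
  expect_equal(fc$multiallelic, 1L)
  expect_equal(fc$non_snv, 1L)
  expect_equal(fc$unphased, 1L)
  expect_equal(fc$missing, 1L)
  expect_equal(nHaplotypes(hm), 20L)
})

test_that("MAF threshold arithmetic follows the chosen mode", {
  # singleton among 20 haplotypes: MAF 0.05
  hm <- loadPhasedVcf(fixtures[["filters_vcf"]], mafThreshold = 0.06,
                      mafMode = "global")
  expect_equal(nSites(hm), 2L)
  expect_equal(metadata(hm)$filterCounts$low_maf, 1L)
  # alt count 1 among 200 haplotypes at threshold 0.01 -> dropped
  a <- matrix(0L, nrow = 200L, ncol = 2L)
  a[1L, 1L] <- 1L
  a[1:100, 2L] <- 1L
  hm2 <- HaplotypeMatrix(a, positions = c(10L, 20L))
  expect_equal(nSites(mafFilter(hm2, 0.01, "global")), 1L)
  # any_population mode rescues a site common in one population
  a3 <- matrix(0L, nrow = 200L, ncol = 1L)
  a3[1:6, 1L] <- 1L  # 6/100 in pop A, 0/100 in pop B; global 0.03
  hm3 <- HaplotypeMatrix(a3, positions = 10L,
                         populations = rep(c("A", "B"), each = 100L))
  expect_equal(nSites(mafFilter(hm3, 0.05, "any_population")), 1L)
  expect_equal(nSites(mafFilter(hm3, 0.05, "global")), 0L)
})

test_that("MAF filtering is idempotent and allele counts are conserved", {
  set.seed(5)
  a <- matrix(rbinom(50L * 40L, 1L, 0.3), nrow = 50L)
  hm <- HaplotypeMatrix(a, positions = seq_len(40L) * 10L,
                        populations = rep(c("P1", "P2"), 25L))
  f1 <- mafFilter(hm, 0.1, "global")
  f2 <- mafFilter(f1, 0.1, "global")
  expect_identical(alleleMatrix(f1), alleleMatrix(f2))
  am <- alleleMatrix(f1)
  expect_true(all(colSums(am == 1L) + colSums(am == 0L) == nHaplotypes(f1)))
})

test_that("population maps select samples and label haplotypes", {
  hm <- loadPhasedVcf(fixtures[["toy_vcf"]], mafThreshold = 0,
                      populations = fixtures[["populations"]])
  expect_equal(nHaplotypes(hm), 20L)
  expect_setequal(unique(populationLabels(hm)), c("AFR", "EUR"))
  expect_equal(sum(populationLabels(hm) == "AFR"), 10L)
  # left haplotype precedes right within a sample
  expect_equal(colData(hm)$sample[1:2], c("S01", "S01"))
  # unknown samples in the map are an error
  expect_error(loadPhasedVcf(fixtures[["toy_vcf"]], mafThreshold = 0,
                             populations = c(NOPE = "AFR")),
               "missing from the VCF header")
})

test_that("loading errors and empty results behave as documented", {
  expect_error(loadPhasedVcf(tempfile(), mafThreshold = 0), "cannot read")
  expect_error(loadPhasedVcf(fixtures[["toy_vcf"]], mafThreshold = 0.3),
               "mafMode")
  # a file whose only site is unphased -> empty result with warning, not a crash
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
               "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0|1"), f)
  expect_warning(hm <- loadPhasedVcf(f, mafThreshold = 0), "empty")
  expect_equal(nSites(hm), 0L)
  expect_equal(nHaplotypes(hm), 4L)
  expect_equal(metadata(hm)$filterCounts$unphased, 1L)
})

test_that("genotypeStrings encodes rows in order and rejects bad ranges", {
  hm <- hmFromStrings(c("01100", "01100", "00001"))
  s <- genotypeStrings(hm)
  expect_identical(s, c("01100", "01100", "00001"))
  expect_identical(genotypeStrings(hm, 2:4), c("110", "110", "000"))
  expect_error(genotypeStrings(hm, integer(0)), "empty")
  expect_error(genotypeStrings(hm, 5:3), "forward only")
  expect_error(genotypeStrings(hm, 4:6), "out of bounds")
})

test_that("ms-style blocks parse with block population labels", {
  hm <- loadMsMatrix(fixtures[["ms"]], populationSizes = c(2L, 2L, 2L),
                     regionLength = 1e4)
  expect_equal(dim(alleleMatrix(hm)), c(6L, 4L))
  expect_identical(populationLabels(hm), rep(c("P0", "P1", "P2"), each = 2L))
  expect_identical(genotypeStrings(hm)[3L], "0011")
  expect_error(loadMsMatrix(fixtures[["ms"]], populationSizes = c(2L, 2L)),
               "does not match the haplotype count")
  # positions scaled to the stated region length
  expect_equal(sitePositions(hm), c(1000L, 2500L, 6000L, 9000L))
})

test_that("ms export round-trips through the reader", {
  hm <- hmFromStrings(c("0101", "0011", "1100", "0000"),
                      populations = rep(c("X", "Y"), each = 2L),
                      positions = c(100L, 2000L, 30000L, 400000L))
  f <- tempfile(fileext = ".txt")
  writeMsMatrix(hm, f, regionLength = 1e6)
  back <- loadMsMatrix(f, populationSizes = c(2L, 2L), regionLength = 1e6,
                       labels = c("X", "Y"))
  expect_identical(alleleMatrix(back), alleleMatrix(hm))
  expect_identical(populationLabels(back), populationLabels(hm))
})

test_that("annotations attach per site with 'none' for unlisted sites", {
  hm <- loadPhasedVcf(fixtures[["toy_vcf"]], mafThreshold = 0,
                      annotations = fixtures[["annotations"]])
  expect_identical(annotationClass(hm),
                   c("coding", "none", "noncoding", "coding", "none"))
})
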