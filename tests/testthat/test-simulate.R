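test_that("variant classes are allocated deterministically by largest remainder", {
  cases <- list(
    list(n = 1000L,
         p = c(FIXED_LOW = 0.05, FIXED_HIGH = 0.05, SHARED_POLY = 0.55,
               RARE_SINGLETON = 0.15, INVARIANT = 0.20),
         expected = c(FIXED_LOW = 50L, FIXED_HIGH = 50L, SHARED_POLY = 550L,
                      RARE_SINGLETON = 150L, INVARIANT = 200L)),
    list(n = 97L,
         p = c(FIXED_LOW = 0.05, FIXED_HIGH = 0.05, SHARED_POLY = 0.55,
               RARE_SINGLETON = 0.15, INVARIANT = 0.20),
         expected = c(FIXED_LOW = 5L, FIXED_HIGH = 5L, SHARED_POLY = 53L,
                      RARE_SINGLETON = 15L, INVARIANT = 19L)),
    list(n = 7L,
         p = c(FIXED_LOW = 0.5, FIXED_HIGH = 0.5, SHARED_POLY = 0,
               RARE_SINGLETON = 0, INVARIANT = 0),
         expected = c(FIXED_LOW = 4L, FIXED_HIGH = 3L, SHARED_POLY = 0L,
                      RARE_SINGLETON = 0L, INVARIANT = 0L)))
  for (cs in cases) {
    cohort <- simulateCohort(CohortConfig(nSites = cs$n,
                                          classProportions = cs$p,
                                          seed = 11))
    counts <- table(factor(cohortTruth(cohort)$class,
                           levels = names(cs$expected)))
    expect_equal(as.integer(counts), unname(cs$expected))
    expect_equal(sum(counts), cs$n)
  }
})

test_that("all-invariant error-free cohort has no alternative reads", {
  cfg <- CohortConfig(nSites = 60, errorRate = 0,
                      classProportions = c(FIXED_LOW = 0, FIXED_HIGH = 0,
                                           SHARED_POLY = 0,
                                           RARE_SINGLETON = 0,
                                           INVARIANT = 1),
                      seed = 3)
  cohort <- simulateCohort(cfg)
  expect_true(all(cohortPileups(cohort)$alt_count == 0))
})

test_that("error-free fixed sites carry only alt reads in the fixed group", {
  cfg <- CohortConfig(nSites = 40, errorRate = 0,
                      classProportions = c(FIXED_LOW = 1, FIXED_HIGH = 0,
                                           SHARED_POLY = 0,
                                           RARE_SINGLETON = 0,
                                           INVARIANT = 0),
                      seed = 5)
  cohort <- simulateCohort(cfg)
  p <- merge(cohortPileups(cohort), cohortSamples(cohort), by = "sample_id")
  low <- p[p$group == "LOW_RFI" & p$ref_count + p$alt_count > 0, ]
  high <- p[p$group == "HIGH_RFI", ]
  expect_true(all(low$alt_count == low$ref_count + low$alt_count))
  expect_true(all(high$alt_count == 0))
})

test_that("with no sequencing error, alt reads appear only in carriers", {
  for (s in c(2L, 9L)) {
    cohort <- simulateCohort(CohortConfig(nSites = 120, errorRate = 0,
                                          seed = s))
    truth <- cohortTruth(cohort)
    p <- cohortPileups(cohort)
    dosage <- truth[, cohortSamples(cohort)$sample_id]
    dosageLong <- unlist(dosage, use.names = FALSE)  # column-major = sample blocks
    expect_true(all(p$alt_count[dosageLong == 0] == 0))
  }
})

test_that("muscle/liver empirical depth ratio matches the configured 2.3", {
  cohort <- simulateCohort(CohortConfig(nSites = 1000, seed = 1))
  p <- merge(cohortPileups(cohort), cohortSamples(cohort), by = "sample_id")
  depth <- p$ref_count + p$alt_count
  ratio <- mean(depth[p$tissue == "MUSCLE"]) / mean(depth[p$tissue == "LIVER"])
  expect_gte(ratio, 2.3 * 0.85)
  expect_lte(ratio, 2.3 * 1.15)
})

test_that("simulation is reproducible from config and seed", {
  cfg <- CohortConfig(nSites = 150, seed = 17)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(cohortPileups(a), cohortPileups(b))
  expect_identical(cohortTruth(a), cohortTruth(b))
  c2 <- simulateCohort(CohortConfig(nSites = 150, seed = 18))
  expect_false(identical(cohortPileups(a), cohortPileups(c2)))
})

test_that("truth class structure honors the class invariants", {
  cohort <- simulateCohort(CohortConfig(nSites = 400, seed = 21))
  truth <- cohortTruth(cohort)
  samples <- cohortSamples(cohort)
  dosage <- as.matrix(truth[, samples$sample_id])
  isLow <- samples$group == "LOW_RFI"
  fl <- truth$class == "FIXED_LOW"
  expect_true(all(dosage[fl, isLow] > 0))
  expect_true(all(dosage[fl, !isLow] == 0))
  fh <- truth$class == "FIXED_HIGH"
  expect_true(all(dosage[fh, !isLow] > 0))
  expect_true(all(dosage[fh, isLow] == 0))
  rs <- truth$class == "RARE_SINGLETON"
  expect_true(all(rowSums(dosage[rs, , drop = FALSE] > 0) == 1))
  inv <- truth$class == "INVARIANT"
  expect_true(all(dosage[inv, ] == 0))
  expect_true(all(truth$ref != truth$alt))
  expect_true(all(diff(truth$pos) >= 10))
})

test_that("truth table round-trips through TSV", {
  cohort <- simulateCohort(CohortConfig(nPerGroupPerTissue = 3,
                                        nSites = 3, seed = 8))
  truth <- cohortTruth(cohort)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTruth(truth, f)
  lines <- readLines(f)
  expect_length(lines, 4L)  # header + 3 sites
  expect_length(strsplit(lines[1], "\t")[[1]], 8L + 12L)  # 12 dosage columns
  expect_identical(readTruth(f), truth)
})

test_that("truth I/O rejects empty and malformed input with line numbers", {
  expect_error(writeTruth(data.frame(), tempfile()), "empty")
  f <- withr::local_tempfile(fileext = ".tsv")
  cohort <- simulateCohort(CohortConfig(nSites = 4, seed = 8))
  writeTruth(cohortTruth(cohort), f)
  lines <- readLines(f)
  writeLines(c(lines[1:3], "broken\trow"), f)
  expect_error(readTruth(f), "line 4")
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(CohortConfig(errorRate = 0.7), "errorRate")
  expect_error(CohortConfig(nSites = 0), "nSites")
  expect_error(CohortConfig(muscleDepthRatio = -1), "muscleDepthRatio")
  expect_error(CohortConfig(classProportions = c(FIXED_LOW = 0.6,
                                                 FIXED_HIGH = 0.6,
                                                 SHARED_POLY = 0,
                                                 RARE_SINGLETON = 0,
                                                 INVARIANT = 0)),
               "classProportions")
  expect_error(CohortConfig(gapFraction = 1.2), "gapFraction")
})

test_that("flat key-value config files are parsed into configurations", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "n_sites = 80", "seed = 12",
               "mean_depth_liver = 7.5", "muscle_depth_ratio = 2.0",
               paste0("class_proportions = FIXED_LOW:0.1,FIXED_HIGH:0.1,",
                      "SHARED_POLY:0.5,RARE_SINGLETON:0.1,INVARIANT:0.2")), f)
  cfg <- readCohortConfig(f)
  expect_s4_class(cfg, "CohortConfig")
  expect_identical(cohortConfig(simulateCohort(cfg))@nSites, 80L)
  writeLines("bogus_key = 3", f)
  expect_error(readCohortConfig(f), "bogus_key")
})
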