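# two-group call set with prescribed genotypes
twoGroupCallSet <- function(lowGt, highGt) {
  gt <- cbind(LOW_RFI = lowGt, HIGH_RFI = highGt)
  n <- length(lowGt)
  ad <- matrix(5L, n, 2, dimnames = list(NULL, colnames(gt)))
  simpleCallSet(adRef = ad, adAlt = ad, gt = gt)
}

test_that("presence in a group means at least one alt allele in its GT", {
  cs <- twoGroupCallSet(
    lowGt = c("0/1", "0/1", "0/0", "./.", "1/1", "0/0"),
    highGt = c("0/1", "0/0", "0/1", "1/1", "./.", "0/0"))
  expect_warning(p <- identifyFixedVariants(cs), "neither group")
  keys <- variantKeys(cs)
  expect_setequal(uniqueLow(p), keys[c(2, 5)])    # hom-ref or missing high
  expect_setequal(uniqueHigh(p), keys[c(3, 4)])
  expect_setequal(sharedKeys(p), keys[1])
  ct <- partitionCounts(p)
  expect_equal(ct[["total"]], 5L)                 # neither-group record out
})

test_that("all-het records are all shared", {
  cs <- twoGroupCallSet(rep("0/1", 4), rep("0/1", 4))
  p <- identifyFixedVariants(cs)
  expect_length(sharedKeys(p), 4L)
  expect_length(uniqueLow(p), 0L)
  expect_length(uniqueHigh(p), 0L)
})

test_that("swapping group labels swaps the unique sets exactly", {
  set.seed(55)
  gts <- c("0/0", "0/1", "1/1", "./.")
  cs <- twoGroupCallSet(sample(gts, 60, replace = TRUE),
                        sample(gts, 60, replace = TRUE))
  p1 <- suppressWarnings(identifyFixedVariants(cs))
  p2 <- suppressWarnings(
    identifyFixedVariants(cs, lowLabel = "HIGH_RFI", highLabel = "LOW_RFI"))
  expect_setequal(uniqueLow(p1), uniqueHigh(p2))
  expect_setequal(uniqueHigh(p1), uniqueLow(p2))
  expect_setequal(sharedKeys(p1), sharedKeys(p2))
})

test_that("partition counts reproduce the worked fixed-SNP arithmetic", {
  p <- new("GroupPartition",
           uniqueLow = sprintf("1:%d:A:G", seq_len(13145)),
           uniqueHigh = sprintf("2:%d:A:G", seq_len(14663)),
           shared = sprintf("3:%d:A:G", seq_len(387816)))
  ct <- partitionCounts(p)
  expect_equal(ct[["unique_low"]], 13145L)
  expect_equal(ct[["unique_high"]], 14663L)
  expect_equal(ct[["shared"]], 387816L)
  expect_equal(ct[["total"]], 415624L)
})

test_that("group partitioning requires two labeled genotypes", {
  cohort <- simulateCohort(CohortConfig(nSites = 20, seed = 2))
  i <- callVariants(cohortPileups(cohort),
                    buildScheme(cohortSamples(cohort), "NON_MERGED"))
  expect_error(identifyFixedVariants(i), "exactly 2")
  cs <- twoGroupCallSet("0/1", "0/0")
  expect_error(identifyFixedVariants(cs, lowLabel = "LO"), "not found")
})

test_that("impact filtering keeps HIGH/MODERATE/MODIFIER by default", {
  imp <- data.frame(key = c("k1", "k2", "k3", "k4"),
                    impact = c("HIGH", "LOW", "MODIFIER", "MODERATE"))
  kept <- filterByImpact(c("k1", "k2", "k3", "k4"), imp)
  expect_equal(as.character(kept), c("k1", "k3", "k4"))
  # all LOW -> empty
  low <- data.frame(key = c("k1", "k2"), impact = c("LOW", "LOW"))
  expect_length(filterByImpact(c("k1", "k2"), low), 0L)
  # full vocabulary -> identity on annotated keys
  all4 <- filterByImpact(c("k1", "k2", "k3", "k4"), imp,
                         keep = c("HIGH", "MODERATE", "MODIFIER", "LOW"))
  expect_equal(as.character(all4), c("k1", "k2", "k3", "k4"))
  # unannotated variants are dropped and counted
  expect_message(out <- filterByImpact(c("k1", "zzz"), imp), "dropped")
  expect_equal(attr(out, "n_unannotated"), 1L)
  expect_error(filterByImpact("k1", data.frame(key = "k1", impact = "HUGE")),
               "unknown impact")
  expect_error(filterByImpact("k1", imp, keep = character(0)), "non-empty")
})

test_that("impact tables read from TSV and reject unknown categories", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgene_id\tconsequence\timpact",
               "1\t100\tA\tG\tG1\tmissense_variant\tMODERATE",
               "1\t200\tC\tT\tG2\tintron_variant\tMODIFIER"), f)
  imp <- readImpactTable(f)
  expect_equal(imp$key, c("1:100:A:G", "1:200:C:T"))
  writeLines(c("chrom\tpos\tref\talt\tgene_id\tconsequence\timpact",
               "1\t100\tA\tG\tG1\tx\tWEIRD"), f)
  expect_error(readImpactTable(f), "WEIRD")
})

test_that("gene assignment uses inclusive 1-based containment", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "1",
                      start = c(100L, 150L), end = c(200L, 250L))
  m <- assignGenes(c("1:100:A:G", "1:160:A:G", "1:201:A:G", "2:160:A:G"),
                   genes)
  expect_equal(m[["1:100:A:G"]], "A")            # start boundary inclusive
  expect_setequal(m[["1:160:A:G"]], c("A", "B")) # overlapping genes
  expect_equal(m[["1:201:A:G"]], "B")            # past A's end
  expect_length(m[["2:160:A:G"]], 0L)            # chromosome with no genes
})

test_that("SNPs-per-gene summarizes counts over genes with assignments", {
  m <- list(a = "G1", b = c("G1", "G2"), c = "G2", d = "G2")
  s <- snpsPerGene(m)
  expect_equal(s$mean, 2.5)        # G1: {a,b}, G2: {b,c,d} -> counts 2, 3
  expect_equal(s$counts, c(G1 = 2L, G2 = 3L))
  expect_equal(s$sd, roundHalfUp(stats::sd(c(2, 3)), 3))
  # hand-computed case: counts {1,2,3}
  m2 <- list(a = "X", b = "Y", c = "Y", d = "Z", e = "Z", f = "Z")
  s2 <- snpsPerGene(m2)
  expect_equal(s2$mean, 2.000)
  expect_equal(s2$sd, 1.000)
  # a single gene: SD 0 by convention
  s3 <- snpsPerGene(list(a = "G", b = "G", c = "G", d = "G", e = "G"))
  expect_equal(s3$mean, 5.000)
  expect_equal(s3$sd, 0.000)
  expect_error(snpsPerGene(list(a = character(0))), "no variant")
})

test_that("filtered fixed sites recover the simulated group truth", {
  cfg <- CohortConfig(nSites = 300, errorRate = 0, seed = 13)
  cohort <- simulateCohort(cfg)
  calls <- callVariants(cohortPileups(cohort),
                        buildScheme(cohortSamples(cohort),
                                    "MERGED_BY_GROUP"), label = "iii")
  filtered <- applyFilters(calls, FilterConfig())$calls
  p <- suppressWarnings(identifyFixedVariants(filtered))
  truth <- cohortTruth(cohort)
  tk <- truthKeys(truth)
  survivingFixedLow <- intersect(tk[truth$class == "FIXED_LOW"],
                                 variantKeys(filtered))
  expect_gt(length(survivingFixedLow), 0L)
  expect_true(all(survivingFixedLow %in% uniqueLow(p)))
  expect_length(intersect(survivingFixedLow, uniqueHigh(p)), 0L)
})
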