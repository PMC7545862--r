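test_that("three-way partitions count and percentage exactly", {
  res <- partitionVariants(c("1:10:A:G", "1:20:C:T"),
                           c("1:20:C:T", "1:30:G:A"),
                           labelA = "a", labelB = "b")
  expect_equal(res$n_unique_a, 1L)
  expect_equal(res$n_shared, 1L)
  expect_equal(res$n_unique_b, 1L)
  expect_equal(res$total, 3L)
  expect_equal(res$pct_shared, 33.33)

  same <- partitionVariants(c("1:1:A:G", "1:2:A:G"), c("1:1:A:G", "1:2:A:G"))
  expect_equal(same$n_shared, 2L)
  expect_equal(same$pct_shared, 100.00)
  expect_equal(same$n_unique_a + same$n_unique_b, 0L)

  disj <- partitionVariants("1:1:A:G", "1:1:A:C")  # same pos, different alt
  expect_equal(disj$n_shared, 0L)
  expect_equal(c(disj$pct_unique_a, disj$pct_unique_b), c(50.00, 50.00))

  expect_error(partitionVariants(character(0), character(0)), "empty")
  expect_warning(partitionVariants(c("1:1:A:G", "1:1:A:G"), "1:2:C:T"),
                 "duplicate")
})

test_that("partition is symmetric and conserves counts", {
  set.seed(77)
  a <- sprintf("1:%d:A:G", sample(1000, 300))
  b <- sprintf("1:%d:A:G", sample(1000, 300))
  ab <- partitionVariants(a, b)
  ba <- partitionVariants(b, a)
  expect_equal(ab$n_unique_a, ba$n_unique_b)
  expect_equal(ab$n_shared, ba$n_shared)
  expect_equal(ab$total,
               ab$n_unique_a + ab$n_shared + ab$n_unique_b)
  expect_equal(ab$total, length(union(a, b)))
  expect_lte(abs(ab$pct_unique_a + ab$pct_shared + ab$pct_unique_b - 100),
             0.02)
})

test_that("mean shared percentage averages partition rows", {
  expect_equal(meanSharedPercentage(data.frame(pct_shared = c(0, 100))),
               50.00)
  expect_equal(meanSharedPercentage(data.frame(pct_shared = 42.42)), 42.42)
  expect_error(meanSharedPercentage(data.frame()), "no comparison")
})

test_that("depth summaries use interpolated quantiles and sample SD", {
  s <- depthSummary(c(2, 4, 6))
  expect_equal(s$minimum, 2)
  expect_equal(s$q1, 3)
  expect_equal(s$median, 4)
  expect_equal(s$q3, 5)
  expect_equal(s$maximum, 6)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)

  one <- depthSummary(7)
  expect_true(all(unlist(one[c("minimum", "q1", "median", "q3",
                               "maximum", "mean")]) == 7))
  expect_equal(one$sd, 0)
  expect_error(depthSummary(numeric(0)), "empty")

  b <- defaultBundle()
  expect_true(all(s$minimum <= s$q1 & s$q1 <= s$median &
                    s$median <= s$q3 & s$q3 <= s$maximum))
  ds <- b$depthSummaries
  expect_true(all(ds$minimum <= ds$q1 & ds$q1 <= ds$median &
                    ds$median <= ds$q3 & ds$q3 <= ds$maximum))
})

test_that("Cohen's d uses the unequal-variance denominator", {
  expect_equal(cohensDQual(c(1, 2, 3), c(4, 5, 6)), 3.000)
  expect_equal(cohensDQual(c(1, 2, 3), c(1, 2, 3)), 0.000)
  # scale invariance
  set.seed(12)
  qa <- rnorm(40, 50, 5); qb <- rnorm(40, 60, 9)
  expect_equal(cohensDQual(qa, qb), cohensDQual(3.7 * qa, 3.7 * qb))
  expect_error(cohensDQual(1, c(1, 2)), "at least 2")
  expect_error(cohensDQual(c(2, 2), c(2, 2)), "zero pooled variance")
})

test_that("Cohen's d equals exact rational arithmetic on integer samples", {
  set.seed(31)
  for (rep in 1:25) {
    na <- sample(2:12, 1); nb <- sample(2:12, 1)
    a <- sample(0:50, na, replace = TRUE)
    b <- sample(0:50, nb, replace = TRUE)
    Sa <- sum(a); Sb <- sum(b)
    # sample variance as an exact fraction: (n*SS - S^2) / (n^2 (n-1))
    vaNum <- na * sum(a^2) - Sa^2; vaDen <- na * (na - 1)
    vbNum <- nb * sum(b^2) - Sb^2; vbDen <- nb * (nb - 1)
    if (vaNum == 0 && vbNum == 0) next
    # d^2 = (Sa/na - Sb/nb)^2 / ((va + vb)/2), all in integer arithmetic
    diffNum <- Sa * nb - Sb * na               # over na*nb
    d2 <- (diffNum^2 / (na * nb)^2) /
      ((vaNum / vaDen + vbNum / vbDen) / 2)
    expect_equal(cohensDQual(a, b), roundHalfUp(sqrt(d2), 3))
  }
})

test_that("genotype AAF counts alt alleles over called genotypes", {
  gt <- rbind(c("0/1", "0/0", "0/0"),
              c("1/1", "0/1", "./."),
              c("./.", "./.", "./."))
  cs <- simpleCallSet(adRef = matrix(5L, 3, 3), adAlt = matrix(2L, 3, 3),
                      gt = gt)
  aaf <- genotypeAAF(cs)
  expect_equal(aaf[1], 1 / 6)
  expect_equal(aaf[2], 3 / 4)
  expect_true(is.na(aaf[3]))
})

test_that("sharing curves bin by AAF and report per-bin overlap", {
  # 4 variants with AAF 0.1, 0.1, 0.9, 0.9 among 5 genotypes; only the two
  # high-frequency ones are in the other set
  gtLow <- c("0/1", "0/0", "0/0", "0/0", "0/0")
  gtHigh <- c("0/1", "1/1", "1/1", "1/1", "1/1")
  gt <- rbind(gtLow, gtLow, gtHigh, gtHigh)
  cs <- simpleCallSet(adRef = matrix(5L, 4, 5), adAlt = matrix(5L, 4, 5),
                      gt = gt, pos = c(10L, 20L, 30L, 40L))
  curve <- aafSharingCurve(cs, variantKeys(cs)[3:4], binWidth = 0.5)
  expect_equal(curve$n, c(2L, 2L))
  expect_equal(curve$pct_shared, c(0, 100))

  full <- aafSharingCurve(cs, variantKeys(cs), binWidth = 0.5)
  expect_equal(full$pct_shared, c(100, 100))
  none <- aafSharingCurve(cs, "2:1:A:G", binWidth = 0.5)
  expect_equal(none$pct_shared, c(0, 0))

  expect_error(aafSharingCurve(cs, cs, binWidth = 0.3), "divide 1")
  allMissing <- simpleCallSet(adRef = matrix(0L, 1, 2),
                              adAlt = matrix(0L, 1, 2),
                              gt = rbind(c("./.", "./.")))
  expect_warning(aafSharingCurve(allMissing, "1:1:A:G", binWidth = 0.5),
                 "skipped")
})

test_that("AAF = 1 lands in the last (right-closed) bin", {
  cs <- simpleCallSet(adRef = matrix(0L, 1, 2), adAlt = matrix(6L, 1, 2),
                      gt = rbind(c("1/1", "1/1")))
  curve <- aafSharingCurve(cs, variantKeys(cs), binWidth = 0.1)
  expect_equal(curve$n[10], 1L)
  expect_equal(sum(curve$n), 1L)
})
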