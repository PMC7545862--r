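## Comparison battery between approach call sets: set partitions, depth
## summaries, quality effect sizes and allele-frequency sharing curves.

.asKeys <- function(x, what = "call set") {
  k <- variantKeys(x)
  if (anyDuplicated(k)) {
    warning("duplicate variant keys in ", what, " collapsed")
    k <- unique(k)
  }
  k
}

#' Three-way partition of two variant sets
#'
#' Partitions the union of two call sets into variants unique to the first,
#' shared, and unique to the second, keyed by exact `(chrom, pos, ref, alt)`
#' identity — the same position with a different alternative allele is a
#' different variant. Percentages are of the union total, rounded half away
#' from zero to two decimals.
#'
#' @param a,b [CallSet] objects or character vectors of variant keys.
#' @param labelA,labelB labels for the two sets (default: call-set labels).
#' @return a one-row data.frame: `label_a`, `label_b`, `n_unique_a`,
#'   `n_shared`, `n_unique_b`, `total`, `pct_unique_a`, `pct_shared`,
#'   `pct_unique_b`.
#' @seealso [meanSharedPercentage()]
#' @examples
#' partitionVariants(c("1:1:A:G", "1:2:C:T"), c("1:2:C:T", "1:3:G:A"))
#' @export
partitionVariants <- function(a, b, labelA = NULL, labelB = NULL) {
  if (is.null(labelA)) labelA <- if (is(a, "CallSet")) callLabel(a) else "A"
  if (is.null(labelB)) labelB <- if (is(b, "CallSet")) callLabel(b) else "B"
  ka <- .asKeys(a, "first set")
  kb <- .asKeys(b, "second set")
  nShared <- length(intersect(ka, kb))
  nA <- length(ka) - nShared
  nB <- length(kb) - nShared
  total <- nA + nShared + nB
  if (total == 0L) stop("both variant sets are empty", call. = FALSE)
  data.frame(label_a = labelA, label_b = labelB,
             n_unique_a = nA, n_shared = nShared, n_unique_b = nB,
             total = total,
             pct_unique_a = roundHalfUp(100 * nA / total, 2),
             pct_shared = roundHalfUp(100 * nShared / total, 2),
             pct_unique_b = roundHalfUp(100 * nB / total, 2),
             stringsAsFactors = FALSE)
}

#' Mean shared percentage over a set of partitions
#'
#' @param results data.frame of [partitionVariants()] rows.
#' @return arithmetic mean of `pct_shared`, two decimals.
#' @examples
#' meanSharedPercentage(data.frame(pct_shared = c(76.20, 74.43, 72.84, 86.70)))
#' @export
meanSharedPercentage <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("no comparison results supplied", call. = FALSE)
  }
  roundHalfUp(mean(results$pct_shared), 2)
}

#' Per-variant read-depth summary
#'
#' Order statistics (minimum, quartiles by linear interpolation, maximum),
#' mean and sample standard deviation of the per-variant site read depth of
#' a call set (sum of genotype depths at each record).
#'
#' @param calls a [CallSet], or a numeric vector of per-variant depths.
#' @return one-row data.frame: `minimum`, `q1`, `median`, `q3`, `maximum`,
#'   `mean`, `sd` (SD is 0 for a single record).
#' @examples
#' depthSummary(c(2, 4, 6))
#' @export
depthSummary <- function(calls) {
  dp <- if (is(calls, "CallSet")) siteDepth(calls) else as.numeric(calls)
  if (length(dp) == 0L) stop("empty call set", call. = FALSE)
  q <- stats::quantile(dp, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(minimum = min(dp), q1 = q[1L], median = q[2L], q3 = q[3L],
             maximum = max(dp), mean = mean(dp), sd = .sampleSD(dp))
}

#' Cohen's d effect size on site quality (unequal variances)
#'
#' Standardized mean difference of Phred site quality between two call sets
#' using the unequal-variance (Welch) denominator:
#' `d = |mean(QUAL_a) - mean(QUAL_b)| / sqrt((s_a^2 + s_b^2) / 2)` with
#' sample variances. Reported as a magnitude, rounded half away from zero to
#' three decimals.
#'
#' @param a,b [CallSet] objects or numeric QUAL vectors, each with at least
#'   two values.
#' @return the effect size (numeric scalar).
#' @examples
#' cohensDQual(c(1, 2, 3), c(4, 5, 6))   # 3.000
#' @export
cohensDQual <- function(a, b) {
  qa <- if (is(a, "CallSet")) qualScores(a) else as.numeric(a)
  qb <- if (is(b, "CallSet")) qualScores(b) else as.numeric(b)
  if (length(qa) < 2L || length(qb) < 2L) {
    stop("both sets need at least 2 records", call. = FALSE)
  }
  denom <- sqrt((stats::var(qa) + stats::var(qb)) / 2)
  if (denom == 0) stop("zero pooled variance", call. = FALSE)
  roundHalfUp(abs(mean(qa) - mean(qb)) / denom, 3)
}

#' Genotype-based alternative allele frequency of call-set records
#'
#' AAF per record is the alternative-allele dosage summed over called
#' genotypes divided by `2 * number of non-missing genotypes` — the
#' sample-frequency notion used by the sharing curves, distinct from the
#' read-based AAF of the filter cascade.
#'
#' @param calls a [CallSet].
#' @return numeric vector of AAF in \[0, 1\] (NA where all genotypes are
#'   missing).
#' @export
genotypeAAF <- function(calls) {
  if (nVariants(calls) == 0L) return(numeric(0))
  dose <- matrix(match(calls@gt, c("0/0", "0/1", "1/1")) - 1L,
                 nrow = nrow(calls@gt))
  called <- rowSums(!is.na(dose))
  ifelse(called > 0, rowSums(dose, na.rm = TRUE) / (2 * called), NA_real_)
}

#' Allele-frequency sharing curve between two call sets
#'
#' Bins the reference call set's records by genotype-based alternative
#' allele frequency ([genotypeAAF()]) and reports, per bin, how many records
#' fall in it and what percentage of them are also present (by variant key)
#' in the other call set. Bins partition \[0, 1\] as
#' `[0, w), [w, 2w), ..., [1 - w, 1]`.
#'
#' @param reference a [CallSet] with called genotypes.
#' @param other a [CallSet] or character vector of variant keys.
#' @param binWidth bin width; must divide 1 evenly.
#' @return data.frame `bin_low`, `bin_high`, `n`, `pct_shared` (NA for
#'   empty bins).
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 200, seed = 5))
#' s <- cohortSamples(cohort)
#' i3 <- callVariants(cohortPileups(cohort),
#'                    buildScheme(s, "MERGED_BY_GROUP"), label = "iii")
#' i1 <- callVariants(cohortPileups(cohort),
#'                    buildScheme(s, "NON_MERGED"), label = "i")
#' aafSharingCurve(i1, i3, binWidth = 0.25)
#' @export
aafSharingCurve <- function(reference, other, binWidth = 0.1) {
  if (!is(reference, "CallSet") || nVariants(reference) == 0L) {
    stop("reference must be a non-empty CallSet", call. = FALSE)
  }
  nBins <- 1 / binWidth
  if (abs(nBins - round(nBins)) > 1e-9) {
    stop("binWidth must divide 1 evenly", call. = FALSE)
  }
  nBins <- as.integer(round(nBins))
  aaf <- genotypeAAF(reference)
  keys <- variantKeys(reference)
  if (anyNA(aaf)) {
    warning(sum(is.na(aaf)), " record(s) with all genotypes missing skipped")
    keys <- keys[!is.na(aaf)]
    aaf <- aaf[!is.na(aaf)]
  }
  bin <- pmin(nBins, floor(aaf / binWidth) + 1L)   # right-closed last bin
  inOther <- keys %in% variantKeys(other)
  n <- tabulate(bin, nbins = nBins)
  sharedN <- vapply(seq_len(nBins),
                    function(b) sum(inOther[bin == b]), integer(1))
  data.frame(bin_low = (seq_len(nBins) - 1L) * binWidth,
             bin_high = seq_len(nBins) * binWidth,
             n = n,
             pct_shared = ifelse(n > 0,
                                 roundHalfUp(100 * sharedN / pmax(n, 1L), 2),
                                 NA_real_))
}
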