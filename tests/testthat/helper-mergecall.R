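# Shared fixtures, built in code.

# CallSet from count matrices (vectors become one genotype column).
simpleCallSet <- function(adRef, adAlt, qual = NULL, gt = NULL,
                          chrom = "1", pos = NULL, ref = "A", altAllele = "G",
                          nearGap = FALSE, nearIndel = FALSE,
                          label = "test") {
  adRef <- as.matrix(adRef)
  adAlt <- as.matrix(adAlt)
  n <- nrow(adRef)
  if (is.null(colnames(adRef))) {
    colnames(adRef) <- colnames(adAlt) <- sprintf("S%d", seq_len(ncol(adRef)))
  }
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(qual)) qual <- rep(100, n)
  if (is.null(gt)) {
    gt <- matrix(ifelse(adRef + adAlt == 0, "./.",
                        ifelse(adAlt > 0, "0/1", "0/0")), nrow = n)
  }
  gt <- as.matrix(gt)
  dimnames(gt) <- list(NULL, colnames(adRef))
  rownames(adRef) <- rownames(adAlt) <- NULL
  CallSet(
    rowdata = data.frame(chrom = chrom, pos = as.integer(pos),
                         ref = rep_len(ref, n), alt = rep_len(altAllele, n),
                         qual = qual,
                         nearGap = rep_len(nearGap, n),
                         nearIndel = rep_len(nearIndel, n),
                         stringsAsFactors = FALSE),
    gt = gt, adRef = adRef, adAlt = adAlt, dp = adRef + adAlt,
    label = label)
}

# site QUAL recomputed from exported likelihoods only (independent of the
# caller's aggregation path)
referenceQual <- function(refCounts, altCounts, errorRate = 0.01) {
  gl <- genotypeLikelihoods(refCounts, altCounts, errorRate)
  informative <- refCounts + altCounts > 0
  min(10000, -10 * sum(log10(gl$posterior0[informative])))
}

# one shared default experiment (study-design cohort, fixed seed), computed
# once per test run
.bundleCache <- new.env(parent = emptyenv())
defaultBundle <- function() {
  if (is.null(.bundleCache$b)) {
    .bundleCache$b <- runExperiment(CohortConfig(seed = 42))
  }
  .bundleCache$b
}

truthKeys <- function(truth) {
  paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
}
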