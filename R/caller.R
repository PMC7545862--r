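## Simplified multi-sample genotype-likelihood caller. A diploid binomial
## model is applied to every genotype column -- including pools of many
## animals, exactly as joint callers treat merged alignment files, which is
## the mechanism behind pooled-sample allele dilution.

.checkErrorRate <- function(errorRate) {
  if (!is.numeric(errorRate) || length(errorRate) != 1L ||
      is.na(errorRate) || errorRate <= 0 || errorRate >= 0.5) {
    stop("errorRate must lie strictly between 0 and 0.5", call. = FALSE)
  }
}

QUAL_CAP <- 10000

## vectorized log-likelihoods and log-posteriors for dosages 0/1/2 under a
## flat prior; rows with depth 0 get logL = 0 (likelihood 1) for every
## dosage, i.e. uninformative
.genotypeLogLik <- function(refCount, altCount, errorRate) {
  n <- refCount + altCount
  pg <- c(errorRate, 0.5, 1 - errorRate)
  logL <- vapply(pg, function(p) stats::dbinom(altCount, n, p, log = TRUE),
                 numeric(length(n)))
  logL <- matrix(logL, ncol = 3L)
  logPost <- logL - .logSumExpRows(logL)
  list(logL = logL, logPost = logPost)
}

#' Genotype likelihoods under the binomial error model
#'
#' For a genotype with `refCount + altCount = n` reads of which `altCount`
#' support the alternative allele, the likelihood of diploid dosage
#' `g in {0, 1, 2}` is `Binomial(altCount; n, p_g)` with
#' `p_g = (g/2) (1 - e) + (1 - g/2) e` for per-read error rate `e`.
#' Likelihoods are computed in log space and normalized to posteriors under
#' a flat prior (1/3 each). A zero-depth genotype is uninformative: all
#' three posteriors are 1/3 and the genotype contributes factor 1 to site
#' quality in [callSite()].
#'
#' @param refCount,altCount non-negative read counts (vectorized).
#' @param errorRate per-read miscall probability, strictly in (0, 0.5).
#' @return a data.frame with columns `logL0`..`logL2` (log-likelihoods) and
#'   `posterior0`..`posterior2` (normalized posteriors summing to 1).
#' @examples
#' genotypeLikelihoods(10, 0, 0.01)$posterior0   # ~0.99892
#' @export
genotypeLikelihoods <- function(refCount, altCount, errorRate = 0.01) {
  .checkErrorRate(errorRate)
  if (any(refCount < 0) || any(altCount < 0)) {
    stop("read counts must be >= 0", call. = FALSE)
  }
  gl <- .genotypeLogLik(refCount, altCount, errorRate)
  post <- exp(gl$logPost)
  data.frame(logL0 = gl$logL[, 1L], logL1 = gl$logL[, 2L],
             logL2 = gl$logL[, 3L],
             posterior0 = post[, 1L], posterior1 = post[, 2L],
             posterior2 = post[, 3L])
}

.GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Call one site from per-genotype pileups
#'
#' Site quality is the Phred-scaled probability that no polymorphism exists:
#' `QUAL = -10 * sum(log10 posterior0_s)` over informative (depth > 0)
#' genotypes, capped at 10,000. Each genotype's call is the
#' maximum-posterior dosage (`"./."` at zero depth). The record is emitted
#' iff `QUAL >= emitThreshold` (default 3.0103, i.e. posterior probability
#' of any variant above 0.5) and at least one alternative read was observed.
#'
#' Adding an alt-carrying genotype can only increase QUAL (quality
#' inflation with sample count), while summing a carrier's reads into a
#' large pool can drive the pooled posterior toward homozygous reference and
#' suppress the site entirely (allele dilution).
#'
#' @param refCounts,altCounts per-genotype read counts at the site.
#' @param chrom,pos,ref,alt site identity (`pos` 1-based).
#' @param nearGap,nearIndel proximity context flags.
#' @param genotypeIds genotype (pool) labels.
#' @param errorRate per-read miscall probability in (0, 0.5).
#' @param emitThreshold minimum QUAL for emission.
#' @return a one-record [CallSet], or `NULL` if the site is not emitted.
#' @examples
#' # a single hom-alt genotype: emitted with QUAL ~199.5
#' callSite(0, 10, errorRate = 0.01)
#' # one het carrier diluted among 6 pooled diploid samples: suppressed
#' callSite(55, 5, errorRate = 0.01)
#' @export
callSite <- function(refCounts, altCounts, chrom = "1", pos = 1L,
                     ref = "A", alt = "G", nearGap = FALSE,
                     nearIndel = FALSE, genotypeIds = NULL,
                     errorRate = 0.01, emitThreshold = 3.0103) {
  .checkErrorRate(errorRate)
  if (length(refCounts) != length(altCounts) || length(refCounts) == 0L) {
    stop("refCounts and altCounts must be non-empty and equal length",
         call. = FALSE)
  }
  if (length(ref) != 1L || length(alt) != 1L || ref == alt) {
    stop("inconsistent ref/alt for site", call. = FALSE)
  }
  if (is.null(genotypeIds)) {
    genotypeIds <- sprintf("S%d", seq_along(refCounts))
  }
  gl <- .genotypeLogLik(refCounts, altCounts, errorRate)
  depth <- refCounts + altCounts
  informative <- depth > 0L
  qual <- min(QUAL_CAP,
              -10 * sum(gl$logPost[informative, 1L] / log(10)))
  if (qual < emitThreshold || sum(altCounts) < 1L) return(NULL)
  gt <- .GT_STRINGS[max.col(gl$logPost, ties.method = "first")]
  gt[!informative] <- "./."
  oneRow <- function(x) matrix(x, nrow = 1L,
                               dimnames = list(NULL, genotypeIds))
  CallSet(
    rowdata = data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                         alt = alt, qual = qual, nearGap = nearGap,
                         nearIndel = nearIndel, stringsAsFactors = FALSE),
    gt = oneRow(gt), adRef = oneRow(as.integer(refCounts)),
    adAlt = oneRow(as.integer(altCounts)),
    dp = oneRow(as.integer(depth)),
    label = "site")
}

#' Joint multi-genotype variant calling over a pileup table
#'
#' Applies [callSite()] to every site of a (pooled or per-sample) pileup
#' table, producing one multi-genotype record per emitted site. When a
#' `PoolingScheme` is supplied, per-sample pileups are pooled with
#' [poolPileups()] first, so the scheme's pools become the genotype columns
#' of the call set — the three merging approaches differ only in this step.
#'
#' @param pileups long pileup data.frame; either per-sample (`sample_id`
#'   column, with `scheme` supplied) or pre-pooled (`pool_id` column).
#' @param scheme optional `PoolingScheme` applied before calling.
#' @param errorRate per-read miscall probability in (0, 0.5).
#' @param emitThreshold minimum QUAL for emission (default 3.0103).
#' @param label label for the resulting [CallSet].
#' @return a [CallSet] of the emitted records, ordered by (chrom, pos, alt).
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 50, seed = 2))
#' sch <- buildScheme(cohortSamples(cohort), "MERGED_BY_GROUP")
#' callVariants(cohortPileups(cohort), sch, label = "iii")
#' @export
callVariants <- function(pileups, scheme = NULL, errorRate = 0.01,
                         emitThreshold = 3.0103, label = "callset") {
  .checkErrorRate(errorRate)
  if (!is.null(scheme)) pileups <- poolPileups(pileups, scheme)
  idCol <- if ("pool_id" %in% names(pileups)) "pool_id" else "sample_id"
  emptyCallSet <- function(ids) {
    emptyMat <- function(mode) matrix(vector(mode, 0), nrow = 0L,
                                      ncol = length(ids),
                                      dimnames = list(NULL, ids))
    CallSet(rowdata = data.frame(chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0),
                                 qual = numeric(0), nearGap = logical(0),
                                 nearIndel = logical(0)),
            gt = emptyMat("character"), adRef = emptyMat("integer"),
            adAlt = emptyMat("integer"), dp = emptyMat("integer"),
            label = label)
  }
  if (nrow(pileups) == 0L) return(emptyCallSet(character(0)))

  al <- .alignPileups(pileups, idCol)
  p <- al$pileups
  nSite <- al$nSite
  nId <- length(al$ids)

  gl <- .genotypeLogLik(p$ref_count, p$alt_count, errorRate)
  depth <- p$ref_count + p$alt_count
  log10post0 <- gl$logPost[, 1L] / log(10)
  log10post0[depth == 0L] <- 0       # uninformative: factor 1

  siteIdx <- rep(seq_len(nSite), times = nId)
  qual <- pmin(QUAL_CAP,
               -10 * rowsum(log10post0, siteIdx, reorder = TRUE)[, 1L])
  altTotal <- rowsum(p$alt_count, siteIdx, reorder = TRUE)[, 1L]
  nearGap <- rowsum(as.integer(p$near_gap), siteIdx, reorder = TRUE)[, 1L] > 0L
  nearIndel <- rowsum(as.integer(p$near_indel), siteIdx,
                      reorder = TRUE)[, 1L] > 0L
  emit <- qual >= emitThreshold & altTotal >= 1L

  if (!any(emit)) return(emptyCallSet(al$ids))

  gt <- .GT_STRINGS[max.col(gl$logPost, ties.method = "first")]
  gt[depth == 0L] <- "./."
  asMat <- function(x) matrix(x, nrow = nSite, ncol = nId,
                              dimnames = list(NULL, al$ids))
  first <- seq_len(nSite)             # site rows of the first id block
  CallSet(
    rowdata = data.frame(chrom = p$chrom[first], pos = p$pos[first],
                         ref = p$ref[first], alt = p$alt[first],
                         qual = unname(qual), nearGap = unname(nearGap),
                         nearIndel = unname(nearIndel),
                         stringsAsFactors = FALSE)[emit, , drop = FALSE],
    gt = asMat(gt)[emit, , drop = FALSE],
    adRef = asMat(p$ref_count)[emit, , drop = FALSE],
    adAlt = asMat(p$alt_count)[emit, , drop = FALSE],
    dp = asMat(depth)[emit, , drop = FALSE],
    label = label)
}
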