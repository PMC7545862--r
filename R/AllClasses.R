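## Central S4 classes. Constructors live next to the class they build;
## accessors and show() methods are in accessors.R.

#' @import methods
NULL

VARIANT_CLASSES <- c("FIXED_LOW", "FIXED_HIGH", "SHARED_POLY",
                     "RARE_SINGLETON", "INVARIANT")
RFI_GROUPS <- c("LOW_RFI", "HIGH_RFI")
TISSUES <- c("LIVER", "MUSCLE")
APPROACHES <- c("NON_MERGED", "MERGED_BY_GROUP_TISSUE", "MERGED_BY_GROUP")
IMPACT_CATEGORIES <- c("HIGH", "MODERATE", "MODIFIER", "LOW")

#' @rdname CohortConfig
#' @export
setClass("CohortConfig",
  representation(
    nPerGroupPerTissue   = "integer",
    nSites               = "integer",
    meanDepthLiver       = "numeric",
    muscleDepthRatio     = "numeric",
    expressionDispersion = "numeric",
    errorRate            = "numeric",
    classProportions     = "numeric",
    gapFraction          = "numeric",
    indelFraction        = "numeric",
    nGenes               = "integer",
    seed                 = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  chk <- function(cond, msg) if (!cond) msgs <<- c(msgs, msg)
  chk(object@nPerGroupPerTissue >= 1L, "field 'nPerGroupPerTissue' must be > 0")
  chk(object@nSites >= 1L, "field 'nSites' must be > 0")
  chk(object@nGenes >= 1L, "field 'nGenes' must be > 0")
  chk(object@meanDepthLiver > 0, "field 'meanDepthLiver' must be > 0")
  chk(object@muscleDepthRatio > 0, "field 'muscleDepthRatio' must be > 0")
  chk(object@expressionDispersion >= 0,
      "field 'expressionDispersion' must be >= 0")
  chk(object@errorRate >= 0 && object@errorRate < 0.5,
      "field 'errorRate' must be in [0, 0.5)")
  chk(object@gapFraction >= 0 && object@gapFraction <= 1,
      "field 'gapFraction' must be in [0, 1]")
  chk(object@indelFraction >= 0 && object@indelFraction <= 1,
      "field 'indelFraction' must be in [0, 1]")
  p <- object@classProportions
  chk(length(p) == length(VARIANT_CLASSES) &&
        setequal(names(p), VARIANT_CLASSES),
      "field 'classProportions' must be named over the five variant classes")
  chk(all(p >= 0) && all(p <= 1),
      "field 'classProportions' entries must be in [0, 1]")
  chk(abs(sum(p) - 1) <= 1e-9, "field 'classProportions' must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Cohort simulation configuration
#'
#' Parameters of the synthetic pileup cohort generator ([simulateCohort()]).
#' Defaults emulate the study design the package is built around: 6 animals
#' per feed-efficiency group (low/high residual feed intake), each sampled in
#' liver and muscle, with muscle sequenced about 2.3 times deeper than liver
#' (the ratio of uniquely-mapped reads between the two tissues in the
#' motivating dataset).
#'
#' @param nPerGroupPerTissue animals per (group, tissue) cell (default 6;
#'   total samples = 2 groups x 2 tissues x this).
#' @param nSites number of simulated variant-candidate sites.
#' @param meanDepthLiver mean per-sample read depth at a liver site for a
#'   gene at average expression.
#' @param muscleDepthRatio multiplicative depth factor for muscle samples.
#' @param expressionDispersion standard deviation, on the natural-log scale,
#'   of the per-gene expression factor multiplying mean depth; the factor is
#'   shared by all sites of a gene.
#' @param errorRate per-read base miscall probability (epsilon).
#' @param classProportions named fractions over the five truth classes
#'   `FIXED_LOW`, `FIXED_HIGH`, `SHARED_POLY`, `RARE_SINGLETON`, `INVARIANT`;
#'   must sum to 1. Sites are allocated deterministically by largest
#'   remainder, so class counts are exact.
#' @param gapFraction fraction of sites flagged as lying within a few bp of
#'   an alignment gap.
#' @param indelFraction fraction of sites flagged as adjacent to an injected
#'   INDEL.
#' @param nGenes number of genes the sites are grouped into.
#' @param seed integer seed; the simulation is byte-reproducible given the
#'   full configuration.
#' @return a `CohortConfig` object.
#' @seealso [simulateCohort()], [readCohortConfig()]
#' @examples
#' cfg <- CohortConfig(nSites = 100, seed = 7)
#' cfg
#' @export
CohortConfig <- function(nPerGroupPerTissue = 6L,
                         nSites = 1000L,
                         meanDepthLiver = 10,
                         muscleDepthRatio = 2.3,
                         expressionDispersion = 0.5,
                         errorRate = 0.01,
                         classProportions = c(FIXED_LOW = 0.05,
                                              FIXED_HIGH = 0.05,
                                              SHARED_POLY = 0.55,
                                              RARE_SINGLETON = 0.15,
                                              INVARIANT = 0.20),
                         gapFraction = 0.05,
                         indelFraction = 0.05,
                         nGenes = 100L,
                         seed = 1L) {
  for (f in c("nPerGroupPerTissue", "nSites", "nGenes", "seed")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != as.integer(v)) {
      stop("invalid configuration: field '", f, "' must be a whole number",
           call. = FALSE)
    }
  }
  new("CohortConfig",
      nPerGroupPerTissue = as.integer(nPerGroupPerTissue),
      nSites = as.integer(nSites),
      meanDepthLiver = meanDepthLiver,
      muscleDepthRatio = muscleDepthRatio,
      expressionDispersion = expressionDispersion,
      errorRate = errorRate,
      classProportions = classProportions[VARIANT_CLASSES],
      gapFraction = gapFraction,
      indelFraction = indelFraction,
      nGenes = as.integer(nGenes),
      seed = as.integer(seed))
}

#' @rdname FilterConfig
#' @export
setClass("FilterConfig",
  representation(
    minDepth    = "numeric",
    minAltReads = "numeric",
    gapWindow   = "numeric",
    minQual     = "numeric",
    indelWindow = "numeric",
    minAAF      = "numeric"
  )
)

setValidity("FilterConfig", function(object) {
  msgs <- character()
  for (f in c("minDepth", "minAltReads", "gapWindow", "minQual",
              "indelWindow", "minAAF")) {
    v <- slot(object, f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      msgs <- c(msgs, paste0("field '", f, "' must be a number >= 0"))
    }
  }
  if (object@minAAF > 1) msgs <- c(msgs, "field 'minAAF' must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Variant filter cascade configuration
#'
#' Thresholds of the six-rule hard-filter cascade applied by
#' [applyFilters()], in application order: minimum site read depth, minimum
#' alternative-allele supporting reads, gap proximity, minimum Phred site
#' quality, INDEL proximity, and minimum read-based alternative allele
#' frequency. Defaults are the cascade used throughout: DP >= 10, >= 2 alt
#' reads, no site within 3 bp of a gap, QUAL >= 30, no site within 5 bp of an
#' INDEL, AAF >= 20%.
#'
#' The gap and INDEL windows are carried for documentation of the proximity
#' predicate; pileups and call sets store the proximity decision as boolean
#' flags (`nearGap`, `nearIndel`) computed or simulated with those windows.
#'
#' @param minDepth minimum total read depth at the site.
#' @param minAltReads minimum reads supporting the alternative allele.
#' @param gapWindow bp window defining gap proximity.
#' @param minQual minimum Phred-scaled site quality.
#' @param indelWindow bp window defining INDEL proximity.
#' @param minAAF minimum site alternative allele frequency (alt reads over
#'   total reads), as a fraction.
#' @return a `FilterConfig` object.
#' @examples
#' FilterConfig()
#' @export
FilterConfig <- function(minDepth = 10, minAltReads = 2, gapWindow = 3,
                         minQual = 30, indelWindow = 5, minAAF = 0.20) {
  new("FilterConfig", minDepth = minDepth, minAltReads = minAltReads,
      gapWindow = gapWindow, minQual = minQual, indelWindow = indelWindow,
      minAAF = minAAF)
}

#' @rdname buildScheme
#' @export
setClass("PoolingScheme",
  representation(
    approach = "character",
    pools    = "list",
    tissue   = "character"
  )
)

setValidity("PoolingScheme", function(object) {
  msgs <- character()
  if (!(object@approach %in% APPROACHES)) {
    msgs <- c(msgs, paste("unknown approach:", object@approach))
  }
  if (length(object@pools) == 0L) msgs <- c(msgs, "scheme has no pools")
  members <- unlist(object@pools, use.names = FALSE)
  if (anyDuplicated(members)) {
    msgs <- c(msgs, "pools are not disjoint")
  }
  if (any(lengths(object@pools) == 0L)) {
    msgs <- c(msgs, "empty pool in scheme")
  }
  if (is.null(names(object@pools)) || anyDuplicated(names(object@pools))) {
    msgs <- c(msgs, "pools must have unique names")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname CallSet
#' @export
setClass("CallSet",
  representation(
    label   = "character",
    rowdata = "data.frame",
    gt      = "matrix",
    adRef   = "matrix",
    adAlt   = "matrix",
    dp      = "matrix"
  )
)

setValidity("CallSet", function(object) {
  msgs <- character()
  rd <- object@rowdata
  need <- c("chrom", "pos", "ref", "alt", "qual", "nearGap", "nearIndel")
  miss <- setdiff(need, names(rd))
  if (length(miss)) {
    return(paste("rowdata missing column(s):", paste(miss, collapse = ", ")))
  }
  n <- nrow(rd)
  for (m in c("gt", "adRef", "adAlt", "dp")) {
    if (nrow(slot(object, m)) != n) {
      msgs <- c(msgs, paste0("matrix '", m, "' row count != variant count"))
    }
    if (!identical(colnames(slot(object, m)), colnames(object@gt))) {
      msgs <- c(msgs, "genotype column names differ across matrices")
    }
  }
  if (n > 0) {
    if (any(rd$qual < 0, na.rm = TRUE)) msgs <- c(msgs, "negative qual")
    if (any(rd$ref == rd$alt)) msgs <- c(msgs, "ref == alt at some site")
    if (any(object@adRef < 0) || any(object@adAlt < 0)) {
      msgs <- c(msgs, "negative allele depth")
    }
    if (!isTRUE(all.equal(object@adRef + object@adAlt, object@dp,
                          check.attributes = FALSE))) {
      msgs <- c(msgs, "AD ref + alt must equal genotype DP")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CallSet of variant records
#'
#' A `CallSet` is a named collection of called variant sites with
#' per-genotype calls, the in-memory analogue of one multi-genotype VCF file.
#' Site-level data (chrom, 1-based pos, ref, alt, Phred `qual`, gap/INDEL
#' proximity flags) live in a row table; per-genotype data are matrices with
#' one column per genotype: `gt` (`"0/0"`, `"0/1"`, `"1/1"` or `"./."`),
#' `adRef`/`adAlt` (allele depths) and `dp` (genotype depth). Site read depth
#' is the row sum of `dp`.
#'
#' @param rowdata data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `nearGap`, `nearIndel`.
#' @param gt,adRef,adAlt,dp per-genotype matrices (rows = variants, columns =
#'   genotypes, identical column names).
#' @param label scenario label (e.g. `"iii"`, `"i_liver"`).
#' @return a `CallSet` object.
#' @seealso [callVariants()], [applyFilters()], [variantKeys()]
#' @export
CallSet <- function(rowdata, gt, adRef, adAlt, dp, label = "callset") {
  rownames(rowdata) <- NULL
  storage.mode(adRef) <- "integer"
  storage.mode(adAlt) <- "integer"
  storage.mode(dp) <- "integer"
  new("CallSet", label = label, rowdata = rowdata, gt = gt,
      adRef = adRef, adAlt = adAlt, dp = dp)
}

#' @rdname identifyFixedVariants
#' @export
setClass("GroupPartition",
  representation(
    uniqueLow  = "character",
    uniqueHigh = "character",
    shared     = "character"
  )
)

setValidity("GroupPartition", function(object) {
  all3 <- c(object@uniqueLow, object@uniqueHigh, object@shared)
  if (anyDuplicated(all3)) {
    "uniqueLow / uniqueHigh / shared must be pairwise disjoint"
  } else TRUE
})

#' @rdname simulateCohort
#' @export
setClass("SyntheticCohort",
  representation(
    samples = "data.frame",
    pileups = "data.frame",
    truth   = "data.frame",
    genes   = "data.frame",
    config  = "CohortConfig"
  )
)

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  if (anyDuplicated(object@samples$sample_id)) {
    msgs <- c(msgs, "sample_id values must be unique")
  }
  cells <- table(object@samples$group, object@samples$tissue)
  if (length(unique(as.vector(cells))) != 1L) {
    msgs <- c(msgs, "every (group, tissue) cell must have the same size")
  }
  if (length(msgs)) msgs else TRUE
})
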