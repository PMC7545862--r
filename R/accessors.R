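## Accessors and show() methods for the S4 classes.

#' Accessors for CallSet objects
#'
#' `nVariants()` gives the number of variant records, `genotypeNames()` the
#' genotype (pool) column labels, `callLabel()` the scenario label,
#' `siteDepth()` the per-site total read depth (sum of genotype DP),
#' `altReads()` the per-site total alternative-supporting reads, `qualScores()`
#' the Phred site qualities, and `variantKeys()` the `"chrom:pos:ref:alt"`
#' identity keys used by all set operations.
#'
#' @param x a [CallSet] object.
#' @return `nVariants()`: integer; `genotypeNames()`/`variantKeys()`:
#'   character vectors; the rest numeric vectors of length `nVariants(x)`.
#' @name CallSet-accessors
#' @aliases nVariants genotypeNames callLabel siteDepth altReads qualScores
#'   variantKeys
#' @examples
#' cs <- CallSet(
#'   rowdata = data.frame(chrom = "1", pos = 5L, ref = "A", alt = "G",
#'                        qual = 40, nearGap = FALSE, nearIndel = FALSE),
#'   gt = matrix("0/1", 1, 1, dimnames = list(NULL, "S1")),
#'   adRef = matrix(5L, 1, 1, dimnames = list(NULL, "S1")),
#'   adAlt = matrix(3L, 1, 1, dimnames = list(NULL, "S1")),
#'   dp = matrix(8L, 1, 1, dimnames = list(NULL, "S1")))
#' variantKeys(cs)
#' siteDepth(cs)
NULL

#' @rdname CallSet-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname CallSet-accessors
#' @export
setMethod("nVariants", "CallSet", function(x) nrow(x@rowdata))

#' @rdname CallSet-accessors
#' @export
setGeneric("genotypeNames", function(x) standardGeneric("genotypeNames"))
#' @rdname CallSet-accessors
#' @export
setMethod("genotypeNames", "CallSet", function(x) colnames(x@gt))

#' @rdname CallSet-accessors
#' @export
setGeneric("callLabel", function(x) standardGeneric("callLabel"))
#' @rdname CallSet-accessors
#' @export
setMethod("callLabel", "CallSet", function(x) x@label)

#' @rdname CallSet-accessors
#' @export
setGeneric("siteDepth", function(x) standardGeneric("siteDepth"))
#' @rdname CallSet-accessors
#' @export
setMethod("siteDepth", "CallSet", function(x) {
  if (nVariants(x) == 0L) integer(0) else as.integer(rowSums(x@dp))
})

#' @rdname CallSet-accessors
#' @export
setGeneric("altReads", function(x) standardGeneric("altReads"))
#' @rdname CallSet-accessors
#' @export
setMethod("altReads", "CallSet", function(x) {
  if (nVariants(x) == 0L) integer(0) else as.integer(rowSums(x@adAlt))
})

#' @rdname CallSet-accessors
#' @export
setGeneric("qualScores", function(x) standardGeneric("qualScores"))
#' @rdname CallSet-accessors
#' @export
setMethod("qualScores", "CallSet", function(x) x@rowdata$qual)

#' @rdname CallSet-accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @rdname CallSet-accessors
#' @export
setMethod("variantKeys", "CallSet", function(x) {
  rd <- x@rowdata
  if (nrow(rd) == 0L) return(character(0))
  paste(rd$chrom, rd$pos, rd$ref, rd$alt, sep = ":")
})
#' @rdname CallSet-accessors
#' @export
setMethod("variantKeys", "character", function(x) x)

#' Subset a CallSet by record index
#'
#' @param x a [CallSet].
#' @param i logical or integer row index.
#' @param j,...,drop ignored (records are rows; genotype columns are kept).
#' @return a [CallSet] with the selected records.
#' @export
setMethod("[", "CallSet", function(x, i, j, ..., drop = FALSE) {
  CallSet(rowdata = x@rowdata[i, , drop = FALSE],
          gt = x@gt[i, , drop = FALSE],
          adRef = x@adRef[i, , drop = FALSE],
          adAlt = x@adAlt[i, , drop = FALSE],
          dp = x@dp[i, , drop = FALSE],
          label = x@label)
})

setMethod("show", "CallSet", function(object) {
  cat("CallSet '", object@label, "': ", nVariants(object), " variant(s), ",
      length(genotypeNames(object)), " genotype(s)\n", sep = "")
  if (nVariants(object) > 0) {
    cat("  genotypes:", paste(genotypeNames(object), collapse = ", "), "\n")
    cat("  QUAL range: [", min(object@rowdata$qual), ", ",
        max(object@rowdata$qual), "]\n", sep = "")
  }
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", 4L * object@nPerGroupPerTissue, "samples (",
      object@nPerGroupPerTissue, "per group x tissue ),",
      object@nSites, "sites,", object@nGenes, "genes\n")
  cat("  depth: liver", object@meanDepthLiver, "x muscle ratio",
      object@muscleDepthRatio, "; dispersion", object@expressionDispersion,
      "; error rate", object@errorRate, "\n")
  cat("  class proportions:",
      paste(names(object@classProportions), object@classProportions,
            sep = "=", collapse = " "), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: DP >=", object@minDepth, "| alt reads >=",
      object@minAltReads, "| no gap within", object@gapWindow,
      "bp | QUAL >=", object@minQual, "| no INDEL within",
      object@indelWindow, "bp | AAF >=", object@minAAF, "\n")
})

#' Accessors for PoolingScheme objects
#'
#' `poolIds()` returns the pool labels, `poolMembers()` the named list
#' mapping pool id to member sample ids, and `schemeApproach()` the merging
#' approach.
#'
#' @param x a `PoolingScheme`.
#' @return character vector, named list, or character scalar respectively.
#' @name PoolingScheme-accessors
#' @aliases poolIds poolMembers schemeApproach
NULL

#' @rdname PoolingScheme-accessors
#' @export
setGeneric("poolIds", function(x) standardGeneric("poolIds"))
#' @rdname PoolingScheme-accessors
#' @export
setMethod("poolIds", "PoolingScheme", function(x) names(x@pools))

#' @rdname PoolingScheme-accessors
#' @export
setGeneric("poolMembers", function(x) standardGeneric("poolMembers"))
#' @rdname PoolingScheme-accessors
#' @export
setMethod("poolMembers", "PoolingScheme", function(x) x@pools)

#' @rdname PoolingScheme-accessors
#' @export
setGeneric("schemeApproach", function(x) standardGeneric("schemeApproach"))
#' @rdname PoolingScheme-accessors
#' @export
setMethod("schemeApproach", "PoolingScheme", function(x) x@approach)

setMethod("show", "PoolingScheme", function(object) {
  cat("PoolingScheme (", object@approach, "): ", length(object@pools),
      " pool(s)\n", sep = "")
  for (p in names(object@pools)) {
    cat("  ", p, ": ", length(object@pools[[p]]), " sample(s)\n", sep = "")
  }
})

#' Accessors for GroupPartition objects
#'
#' Variant keys fixed within the low group (`uniqueLow()`), fixed within the
#' high group (`uniqueHigh()`), present in both (`sharedKeys()`), and the
#' three counts plus total (`partitionCounts()`).
#'
#' @param x a [GroupPartition].
#' @return character vectors of keys, or for `partitionCounts()` a named
#'   integer vector `c(unique_low, unique_high, shared, total)`.
#' @name GroupPartition-accessors
#' @aliases uniqueLow uniqueHigh sharedKeys partitionCounts
NULL

#' @rdname GroupPartition-accessors
#' @export
setGeneric("uniqueLow", function(x) standardGeneric("uniqueLow"))
#' @rdname GroupPartition-accessors
#' @export
setMethod("uniqueLow", "GroupPartition", function(x) x@uniqueLow)

#' @rdname GroupPartition-accessors
#' @export
setGeneric("uniqueHigh", function(x) standardGeneric("uniqueHigh"))
#' @rdname GroupPartition-accessors
#' @export
setMethod("uniqueHigh", "GroupPartition", function(x) x@uniqueHigh)

#' @rdname GroupPartition-accessors
#' @export
setGeneric("sharedKeys", function(x) standardGeneric("sharedKeys"))
#' @rdname GroupPartition-accessors
#' @export
setMethod("sharedKeys", "GroupPartition", function(x) x@shared)

#' @rdname GroupPartition-accessors
#' @export
setGeneric("partitionCounts", function(x) standardGeneric("partitionCounts"))
#' @rdname GroupPartition-accessors
#' @export
setMethod("partitionCounts", "GroupPartition", function(x) {
  c(unique_low = length(x@uniqueLow),
    unique_high = length(x@uniqueHigh),
    shared = length(x@shared),
    total = length(x@uniqueLow) + length(x@uniqueHigh) + length(x@shared))
})

setMethod("show", "GroupPartition", function(object) {
  ct <- partitionCounts(object)
  cat("GroupPartition: ", ct[["total"]], " variant(s) | unique low ",
      ct[["unique_low"]], " | unique high ", ct[["unique_high"]],
      " | shared ", ct[["shared"]], "\n", sep = "")
})

#' Accessors for SyntheticCohort objects
#'
#' `cohortSamples()` returns the sample sheet (`sample_id`, `group`,
#' `tissue`), `cohortPileups()` the long per-sample per-site pileup table,
#' `cohortTruth()` the truth table with per-sample dosages, `cohortGenes()`
#' the simulated gene intervals, and `cohortConfig()` the generating
#' [CohortConfig].
#'
#' @param x a `SyntheticCohort` from [simulateCohort()].
#' @return a data.frame (or `CohortConfig` for `cohortConfig()`).
#' @name SyntheticCohort-accessors
#' @aliases cohortSamples cohortPileups cohortTruth cohortGenes cohortConfig
NULL

#' @rdname SyntheticCohort-accessors
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))
#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortSamples", "SyntheticCohort", function(x) x@samples)

#' @rdname SyntheticCohort-accessors
#' @export
setGeneric("cohortPileups", function(x) standardGeneric("cohortPileups"))
#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortPileups", "SyntheticCohort", function(x) x@pileups)

#' @rdname SyntheticCohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname SyntheticCohort-accessors
#' @export
setGeneric("cohortGenes", function(x) standardGeneric("cohortGenes"))
#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortGenes", "SyntheticCohort", function(x) x@genes)

#' @rdname SyntheticCohort-accessors
#' @export
setGeneric("cohortConfig", function(x) standardGeneric("cohortConfig"))
#' @rdname SyntheticCohort-accessors
#' @export
setMethod("cohortConfig", "SyntheticCohort", function(x) x@config)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@samples), "samples,",
      nrow(object@truth), "sites,", nrow(object@genes), "genes\n")
  cat("  truth classes:\n")
  print(table(object@truth$class))
})
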