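## Fixed-within-group SNP identification from a two-genotype call set, and
## gene-level summaries of the resulting variant lists.

.hasAlt <- function(gt) gt %in% c("0/1", "1/1")

#' Identify SNPs fixed within one phenotype group
#'
#' From a call set with exactly two group genotypes (one pooled genotype per
#' phenotype group), partitions variants into those present only in the low
#' group, only in the high group, and shared. "Present" means the group's
#' genotype carries at least one alternative allele; "absent" covers both
#' homozygous reference and missing (`"./."`) calls. Records present in
#' neither group are excluded (with a warning).
#'
#' @param calls a [CallSet] with exactly two genotypes labeled `lowLabel`
#'   and `highLabel`.
#' @param lowLabel,highLabel genotype column names of the two groups.
#' @return a [GroupPartition]; the three key sets are pairwise disjoint and
#'   swapping the group labels swaps `uniqueLow`/`uniqueHigh` exactly.
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 100, seed = 4))
#' calls <- callVariants(cohortPileups(cohort),
#'                       buildScheme(cohortSamples(cohort),
#'                                   "MERGED_BY_GROUP"))
#' identifyFixedVariants(calls)
#' @export
identifyFixedVariants <- function(calls, lowLabel = "LOW_RFI",
                                  highLabel = "HIGH_RFI") {
  ids <- genotypeNames(calls)
  if (length(ids) != 2L) {
    stop("call set must have exactly 2 group genotypes, found ",
         length(ids), call. = FALSE)
  }
  miss <- setdiff(c(lowLabel, highLabel), ids)
  if (length(miss)) {
    stop("genotype label(s) not found in call set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  keys <- variantKeys(calls)
  inLow <- .hasAlt(calls@gt[, lowLabel])
  inHigh <- .hasAlt(calls@gt[, highLabel])
  if (any(!inLow & !inHigh)) {
    warning(sum(!inLow & !inHigh),
            " record(s) present in neither group excluded from partition")
  }
  new("GroupPartition",
      uniqueLow = keys[inLow & !inHigh],
      uniqueHigh = keys[!inLow & inHigh],
      shared = keys[inLow & inHigh])
}

#' Read a variant impact annotation table
#'
#' TSV with columns `chrom pos ref alt gene_id consequence impact`, one row
#' per (variant, gene) annotation; `impact` must be one of `HIGH`,
#' `MODERATE`, `MODIFIER`, `LOW`.
#'
#' @param path path to the TSV file.
#' @return data.frame with an additional `key` column (`chrom:pos:ref:alt`).
#' @export
readImpactTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene_id", "consequence", "impact")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("impact table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(d$impact), IMPACT_CATEGORIES)
  if (length(bad)) {
    stop("unknown impact category in table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d$key <- paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  d
}

#' Filter variants by functional impact category
#'
#' Retains variants with at least one annotation whose impact category is in
#' `keep` (default: `HIGH`, `MODERATE`, `MODIFIER` — everything except
#' `LOW`). Variants absent from the annotation table are dropped; their
#' count is attached as attribute `n_unannotated` and reported in a message.
#'
#' @param keys character vector of variant keys (or a [CallSet] /
#'   [GroupPartition] set accessor result).
#' @param impacts impact table from [readImpactTable()] (or any data.frame
#'   with `key` and `impact` columns).
#' @param keep impact categories to retain.
#' @return the retained keys, in input order.
#' @examples
#' imp <- data.frame(key = c("1:1:A:G", "1:2:C:T"),
#'                   impact = c("HIGH", "LOW"))
#' filterByImpact(c("1:1:A:G", "1:2:C:T"), imp)
#' @export
filterByImpact <- function(keys, impacts,
                           keep = c("HIGH", "MODERATE", "MODIFIER")) {
  keys <- variantKeys(keys)
  if (length(keep) == 0L || !all(keep %in% IMPACT_CATEGORIES)) {
    stop("'keep' must be a non-empty subset of: ",
         paste(IMPACT_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(impacts$impact), IMPACT_CATEGORIES)
  if (length(bad)) {
    stop("unknown impact category in table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  annotated <- keys %in% impacts$key
  nUn <- sum(!annotated)
  if (nUn > 0) {
    message(nUn, " variant(s) without impact annotation dropped")
  }
  keptKeys <- unique(impacts$key[impacts$impact %in% keep])
  out <- keys[annotated & keys %in% keptKeys]
  attr(out, "n_unannotated") <- nUn
  out
}

.keysToGRanges <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
}

#' Assign variants to overlapping genes
#'
#' Maps each variant to every gene whose interval contains its position on
#' the same chromosome (1-based inclusive bounds, no flanking window, strand
#' ignored). Overlap is computed with `GenomicRanges::findOverlaps()`.
#'
#' @param keys variant keys (or a [CallSet]).
#' @param genes data.frame of gene intervals (`gene_id`, `chrom`, `start`,
#'   `end`) as from [readGeneIntervals()] or [cohortGenes()].
#' @return named list mapping each variant key to a character vector of
#'   gene ids (empty for unmapped variants).
#' @examples
#' genes <- data.frame(gene_id = c("A", "B"), chrom = "1",
#'                     start = c(100L, 150L), end = c(200L, 250L))
#' assignGenes("1:160:A:G", genes)
#' @export
assignGenes <- function(keys, genes) {
  keys <- variantKeys(keys)
  out <- stats::setNames(rep(list(character(0)), length(keys)), keys)
  if (length(keys) == 0L || nrow(genes) == 0L) return(out)
  vr <- .keysToGRanges(keys)
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(vr, gr)
  sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  out[as.integer(names(sp))] <- sp
  out
}

#' SNPs-per-gene summary
#'
#' Counts assigned SNPs per gene (over genes with at least one assigned
#' SNP) and reports the mean and sample standard deviation of those counts,
#' rounded half away from zero to three decimals (SD 0 for a single gene).
#'
#' @param mapping variant-to-genes mapping from [assignGenes()].
#' @return list with `mean`, `sd`, and `counts` (named per-gene counts).
#' @examples
#' snpsPerGene(list(a = "G1", b = c("G1", "G2"), c = "G2", d = "G2"))
#' @export
snpsPerGene <- function(mapping) {
  genes <- unlist(mapping, use.names = FALSE)
  if (length(genes) == 0L) {
    stop("no variant maps to any gene", call. = FALSE)
  }
  counts <- table(genes)
  list(mean = roundHalfUp(mean(counts), 3),
       sd = roundHalfUp(.sampleSD(as.numeric(counts)), 3),
       counts = stats::setNames(as.integer(counts), names(counts)))
}
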