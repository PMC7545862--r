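## Pooling of per-sample pileups into merged pseudo-samples: the count-level
## analogue of merging BAM files before joint calling.

#' Build a pooling scheme for a merging approach
#'
#' Maps cohort samples to the genotype columns ("pools") that a merging
#' approach calls variants from:
#' \describe{
#'   \item{`NON_MERGED`}{one pool per sample (approach i; with a tissue
#'     restriction, one pool per sample of that tissue, so the default
#'     cohort yields a 12-genotype call per tissue).}
#'   \item{`MERGED_BY_GROUP_TISSUE`}{one pool per (group, tissue) cell
#'     (approach ii; restricted to a tissue: 2 pools, one per group).}
#'   \item{`MERGED_BY_GROUP`}{one pool per group, each holding all liver and
#'     muscle samples of that group (approach iii; 2 pools).}
#' }
#'
#' @param samples sample sheet data.frame with `sample_id`, `group`,
#'   `tissue` columns (see [cohortSamples()]).
#' @param approach one of `"NON_MERGED"`, `"MERGED_BY_GROUP_TISSUE"`,
#'   `"MERGED_BY_GROUP"`.
#' @param tissue optional tissue restriction (`"LIVER"` or `"MUSCLE"`); only
#'   valid for `NON_MERGED` and `MERGED_BY_GROUP_TISSUE`.
#' @return a `PoolingScheme`: disjoint pools covering the (restricted)
#'   samples.
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 10, seed = 1))
#' buildScheme(cohortSamples(cohort), "MERGED_BY_GROUP")
#' @export
buildScheme <- function(samples, approach, tissue = NULL) {
  if (is.null(samples) || nrow(samples) == 0L) {
    stop("no samples supplied", call. = FALSE)
  }
  approach <- match.arg(approach, APPROACHES)
  if (!is.null(tissue)) {
    tissue <- match.arg(tissue, TISSUES)
    if (approach == "MERGED_BY_GROUP") {
      stop("tissue restriction is not valid for MERGED_BY_GROUP ",
           "(it already merges both tissues)", call. = FALSE)
    }
    samples <- samples[samples$tissue == tissue, , drop = FALSE]
    if (nrow(samples) == 0L) {
      stop("empty pool after tissue restriction: ", tissue, call. = FALSE)
    }
  }
  pools <- switch(approach,
    NON_MERGED = as.list(stats::setNames(samples$sample_id,
                                         samples$sample_id)),
    MERGED_BY_GROUP_TISSUE = split(samples$sample_id,
                                   paste(samples$group, samples$tissue,
                                         sep = "_")),
    MERGED_BY_GROUP = split(samples$sample_id, samples$group))
  new("PoolingScheme", approach = approach, pools = pools,
      tissue = if (is.null(tissue)) NA_character_ else tissue)
}

## order a pileup table by (id, chrom, pos, alt) and verify every id carries
## the same site grid; returns the ordered table plus grid size
.alignPileups <- function(pileups, idCol) {
  ord <- order(pileups[[idCol]], pileups$chrom, pileups$pos, pileups$alt)
  p <- pileups[ord, , drop = FALSE]
  ids <- unique(p[[idCol]])
  key <- paste(p$chrom, p$pos, p$ref, p$alt, sep = ":")
  nSite <- length(key) / length(ids)
  if (nSite != as.integer(nSite) ||
      !all(key == rep(key[seq_len(nSite)], times = length(ids)))) {
    stop("mismatched site grids: all samples must carry the same ",
         "(chrom, pos, ref, alt) sites", call. = FALSE)
  }
  list(pileups = p, ids = ids, nSite = as.integer(nSite))
}

#' Pool per-sample pileups according to a scheme
#'
#' For each pool and site, reference and alternative read counts are the sums
#' over member samples (read pooling is exactly additive, the idealized
#' counterpart of merging alignment files), and the gap/INDEL proximity flags
#' are the logical OR over members. Pooled depth therefore equals the sum of
#' member depths at every site, and pooling is associative: pooling a group's
#' tissue-pools equals pooling the group's samples directly.
#'
#' @param pileups long pileup data.frame (`sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `ref_count`, `alt_count`, `near_gap`, `near_indel`), all
#'   samples on the same site grid.
#' @param scheme a `PoolingScheme` from [buildScheme()]; every member sample
#'   must be present in `pileups`.
#' @return a long pileup data.frame with a `pool_id` column in place of
#'   `sample_id`.
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 10, seed = 1))
#' sch <- buildScheme(cohortSamples(cohort), "MERGED_BY_GROUP")
#' pooled <- poolPileups(cohortPileups(cohort), sch)
#' head(pooled)
#' @export
poolPileups <- function(pileups, scheme) {
  members <- unlist(poolMembers(scheme), use.names = FALSE)
  missing <- setdiff(members, unique(pileups$sample_id))
  if (length(missing)) {
    stop("sample(s) in scheme but not in pileups: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pileups <- pileups[pileups$sample_id %in% members, , drop = FALSE]
  al <- .alignPileups(pileups, "sample_id")
  p <- al$pileups
  poolOf <- rep(names(poolMembers(scheme)), lengths(poolMembers(scheme)))
  names(poolOf) <- members
  grp <- paste(poolOf[p$sample_id], rep(seq_len(al$nSite),
                                        times = length(al$ids)), sep = "\r")
  refSum <- rowsum(p$ref_count, grp, reorder = FALSE)
  altSum <- rowsum(p$alt_count, grp, reorder = FALSE)
  gapAny <- rowsum(as.integer(p$near_gap), grp, reorder = FALSE) > 0L
  indelAny <- rowsum(as.integer(p$near_indel), grp, reorder = FALSE) > 0L
  keyRows <- !duplicated(grp)
  out <- data.frame(
    pool_id = poolOf[p$sample_id][keyRows],
    chrom = p$chrom[keyRows],
    pos = p$pos[keyRows],
    ref = p$ref[keyRows],
    alt = p$alt[keyRows],
    ref_count = as.integer(refSum[, 1L]),
    alt_count = as.integer(altSum[, 1L]),
    near_gap = as.vector(gapAny),
    near_indel = as.vector(indelAny),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$pool_id, out$chrom, out$pos, out$alt), , drop = FALSE]
}

#' Write and read pileup tables and pool manifests
#'
#' `writePileups()` writes one TSV per sample (or pool) into `dir`, columns
#' `chrom pos ref alt ref_count alt_count near_gap near_indel`;
#' `readPileups()` reads them back into the long format, taking the sample id
#' from each file name. `writePoolManifest()`/`readPoolManifest()` serialize
#' a [buildScheme()] result as a two-column `pool_id sample_id` TSV.
#'
#' @param pileups long pileup data.frame with a `sample_id` (or `pool_id`)
#'   column.
#' @param dir directory for the per-sample TSV files.
#' @param paths character vector of pileup TSV paths.
#' @param scheme a `PoolingScheme`.
#' @param path manifest file path.
#' @param approach approach label for the reconstructed scheme.
#' @return `readPileups()`: a long pileup data.frame; `readPoolManifest()`:
#'   a `PoolingScheme`; the writers return their target invisibly.
#' @name pileup-io
NULL

#' @rdname pileup-io
#' @export
writePileups <- function(pileups, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idCol <- if ("sample_id" %in% names(pileups)) "sample_id" else "pool_id"
  cols <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count",
            "near_gap", "near_indel")
  for (s in unique(pileups[[idCol]])) {
    utils::write.table(
      pileups[pileups[[idCol]] == s, cols, drop = FALSE],
      file.path(dir, paste0(s, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname pileup-io
#' @export
readPileups <- function(paths) {
  pieces <- lapply(paths, function(f) {
    d <- utils::read.delim(f, stringsAsFactors = FALSE)
    d$chrom <- as.character(d$chrom)
    cbind(sample_id = sub("\\.tsv$", "", basename(f)), d,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' @rdname pileup-io
#' @export
writePoolManifest <- function(scheme, path) {
  df <- data.frame(
    pool_id = rep(poolIds(scheme), lengths(poolMembers(scheme))),
    sample_id = unlist(poolMembers(scheme), use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pileup-io
#' @export
readPoolManifest <- function(path, approach = "NON_MERGED") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("PoolingScheme", approach = approach,
      pools = split(df$sample_id, df$pool_id), tissue = NA_character_)
}
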