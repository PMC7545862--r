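## Synthetic pileup cohort generator: a 2-group x 2-tissue cohort with known
## per-site truth, used to exercise every downstream stage without sequencing
## data.

## deterministic largest-remainder apportionment of n among proportions p;
## ties broken by position so class counts are exactly reproducible
.largestRemainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' Simulate a pileup cohort with known truth
#'
#' Generates per-sample, per-site allele pileups for a two-group
#' (low/high residual feed intake) by two-tissue (liver/muscle) cohort, with
#' sites allocated deterministically among five truth classes:
#' group-fixed alternative alleles (`FIXED_LOW`, `FIXED_HIGH`, homozygous
#' alternative in every sample of that group and absent from the other),
#' mid-frequency shared polymorphisms (`SHARED_POLY`, Hardy-Weinberg dosages
#' at a per-site allele frequency uniform on \[0.2, 0.8\]), rare variants
#' carried heterozygously by exactly one sample (`RARE_SINGLETON`), and
#' invariant sites (`INVARIANT`).
#'
#' Per site and sample, read depth is Poisson with mean
#' `meanDepth(tissue) * geneFactor`, where the log-normal gene expression
#' factor (sd `expressionDispersion` on the log scale, unit mean) is shared
#' by all sites of a gene; the alternative read count is Binomial(depth, p)
#' with `p = (dosage/2) * (1 - errorRate) + (1 - dosage/2) * errorRate`, so
#' sequencing error both creates spurious alternative reads at non-carrier
#' sites and removes support at carrier sites. Gap and INDEL proximity are
#' simulated as boolean context flags on the configured fractions of sites.
#' Sites lie on one synthetic chromosome, 10 bp apart. The simulation is
#' fully reproducible from the configuration (including its seed).
#'
#' @param config a [CohortConfig].
#' @return a `SyntheticCohort` with the sample sheet, the long pileup table
#'   (`sample_id`, `chrom`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`,
#'   `near_gap`, `near_indel`), the truth table (site columns plus one
#'   dosage column per sample), and the simulated gene intervals.
#' @seealso [CohortConfig()], [writeTruth()], [buildScheme()]
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 50, seed = 3))
#' cohort
#' @export
simulateCohort <- function(config) {
  validObject(config)
  withr::with_seed(config@seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
  nPer <- config@nPerGroupPerTissue
  samples <- expand.grid(idx = seq_len(nPer), tissue = TISSUES,
                         group = RFI_GROUPS, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_%02d", sub("_RFI$", "", samples$group),
                        samples$tissue, samples$idx),
    group = samples$group,
    tissue = samples$tissue,
    stringsAsFactors = FALSE)
  nSamp <- nrow(samples)
  nSites <- config@nSites

  pos <- as.integer(seq(1L, by = 10L, length.out = nSites))
  ref <- sample(c("A", "C", "G", "T"), nSites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))

  classCounts <- .largestRemainder(nSites, config@classProportions)
  classes <- sample(rep(VARIANT_CLASSES, times = classCounts))

  geneIdx <- ceiling(seq_len(nSites) * config@nGenes / nSites)
  geneIds <- sprintf("G%04d", seq_len(config@nGenes))
  geneId <- geneIds[geneIdx]
  disp <- config@expressionDispersion
  geneFactor <- exp(stats::rnorm(config@nGenes, mean = -disp^2 / 2, sd = disp))

  nearGap <- rep(FALSE, nSites)
  nearGap[sample.int(nSites, round(config@gapFraction * nSites))] <- TRUE
  nearIndel <- rep(FALSE, nSites)
  nearIndel[sample.int(nSites, round(config@indelFraction * nSites))] <- TRUE

  isLow <- samples$group == "LOW_RFI"
  dosage <- matrix(0L, nrow = nSites, ncol = nSamp,
                   dimnames = list(NULL, samples$sample_id))
  fixedLow <- classes == "FIXED_LOW"
  fixedHigh <- classes == "FIXED_HIGH"
  dosage[fixedLow, isLow] <- 2L
  dosage[fixedHigh, !isLow] <- 2L
  sharedIdx <- which(classes == "SHARED_POLY")
  if (length(sharedIdx)) {
    af <- stats::runif(length(sharedIdx), 0.2, 0.8)
    dosage[sharedIdx, ] <- matrix(
      stats::rbinom(length(sharedIdx) * nSamp, 2L, rep(af, times = nSamp)),
      nrow = length(sharedIdx))
  }
  singletonIdx <- which(classes == "RARE_SINGLETON")
  if (length(singletonIdx)) {
    carrier <- sample.int(nSamp, length(singletonIdx), replace = TRUE)
    dosage[cbind(singletonIdx, carrier)] <- 1L
  }

  meanDepth <- ifelse(samples$tissue == "MUSCLE",
                      config@meanDepthLiver * config@muscleDepthRatio,
                      config@meanDepthLiver)
  lambda <- outer(geneFactor[geneIdx], meanDepth)
  depth <- matrix(stats::rpois(nSites * nSamp, lambda), nrow = nSites)
  eps <- config@errorRate
  pAlt <- eps + (dosage / 2) * (1 - 2 * eps)
  altCount <- matrix(stats::rbinom(nSites * nSamp, depth, pAlt),
                     nrow = nSites)

  pileups <- data.frame(
    sample_id = rep(samples$sample_id, each = nSites),
    chrom = "1",
    pos = rep(pos, times = nSamp),
    ref = rep(ref, times = nSamp),
    alt = rep(alt, times = nSamp),
    ref_count = as.integer(depth - altCount),
    alt_count = as.integer(altCount),
    near_gap = rep(nearGap, times = nSamp),
    near_indel = rep(nearIndel, times = nSamp),
    stringsAsFactors = FALSE)

  truth <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                      class = classes, gene_id = geneId,
                      near_gap = nearGap, near_indel = nearIndel,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(dosage))

  used <- sort(unique(geneIdx))   # with nSites < nGenes some genes get no site
  genes <- data.frame(
    gene_id = geneIds[used],
    chrom = "1",
    start = as.integer(tapply(pos, geneIdx, min)),
    end = as.integer(tapply(pos, geneIdx, max)),
    strand = "+",
    stringsAsFactors = FALSE)

  new("SyntheticCohort", samples = samples, pileups = pileups,
      truth = truth, genes = genes, config = config)
}

.TRUTH_SITE_COLS <- c("chrom", "pos", "ref", "alt", "class", "gene_id",
                      "near_gap", "near_indel")

#' Write and read a cohort truth table
#'
#' The truth table is serialized as TSV with one row per site and one dosage
#' column per sample, after the fixed site columns `chrom pos ref alt class
#' gene_id near_gap near_indel`. Positions are 1-based. `readTruth()` is the
#' exact inverse of `writeTruth()`.
#'
#' @param truth truth data.frame as produced by [simulateCohort()]
#'   (via `cohortTruth()`).
#' @param path file path.
#' @return `writeTruth()` returns `path` invisibly; `readTruth()` returns the
#'   truth data.frame.
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 20, seed = 1))
#' f <- tempfile(fileext = ".tsv")
#' writeTruth(cohortTruth(cohort), f)
#' identical(readTruth(f), cohortTruth(cohort))
#' @export
writeTruth <- function(truth, path) {
  if (is.null(truth) || nrow(truth) == 0L) {
    stop("truth table is empty", call. = FALSE)
  }
  miss <- setdiff(.TRUTH_SITE_COLS, names(truth))
  if (length(miss)) {
    stop("truth table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("truth file has no data rows: ", path, call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  miss <- setdiff(.TRUTH_SITE_COLS, header)
  if (length(miss)) {
    stop("parse error at line 1: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad)) {
    stop("parse error at line ", bad[1L] + 1L, ": expected ",
         length(header), " fields, found ", lengths(fields)[bad[1L]],
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  colnames(m) <- header
  truth <- data.frame(m[, .TRUTH_SITE_COLS, drop = FALSE],
                      stringsAsFactors = FALSE)
  truth$pos <- as.integer(truth$pos)
  truth$near_gap <- as.logical(truth$near_gap)
  truth$near_indel <- as.logical(truth$near_indel)
  if (anyNA(truth$pos)) {
    stop("parse error at line ", which(is.na(truth$pos))[1L] + 1L,
         ": non-integer position", call. = FALSE)
  }
  sampleCols <- setdiff(header, .TRUTH_SITE_COLS)
  for (s in sampleCols) {
    d <- as.integer(m[, s])
    if (anyNA(d)) {
      stop("parse error at line ", which(is.na(d))[1L] + 1L,
           ": non-integer dosage in column ", s, call. = FALSE)
    }
    truth[[s]] <- d
  }
  truth
}

.CONFIG_KEYS <- c(
  n_per_group_per_tissue = "nPerGroupPerTissue",
  n_sites = "nSites",
  mean_depth_liver = "meanDepthLiver",
  muscle_depth_ratio = "muscleDepthRatio",
  expression_dispersion = "expressionDispersion",
  error_rate = "errorRate",
  class_proportions = "classProportions",
  gap_fraction = "gapFraction",
  indel_fraction = "indelFraction",
  n_genes = "nGenes",
  seed = "seed")

#' Read a cohort configuration from a flat key-value file
#'
#' The file holds one `key = value` pair per line (`#` comments and blank
#' lines ignored). Recognized keys are the snake_case forms of the
#' [CohortConfig()] arguments (`n_sites`, `mean_depth_liver`,
#' `muscle_depth_ratio`, `expression_dispersion`, `error_rate`,
#' `gap_fraction`, `indel_fraction`, `n_per_group_per_tissue`, `n_genes`,
#' `seed`, and `class_proportions` as comma-separated `CLASS:fraction`
#' pairs). Unspecified keys keep their defaults.
#'
#' @param path path to the configuration file.
#' @return a [CohortConfig].
#' @examples
#' f <- tempfile()
#' writeLines(c("n_sites = 50", "seed = 9",
#'              paste0("class_proportions = FIXED_LOW:0.5,FIXED_HIGH:0.5,",
#'                     "SHARED_POLY:0,RARE_SINGLETON:0,INVARIANT:0")), f)
#' readCohortConfig(f)
#' @export
readCohortConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      stop("parse error in config line: '", lines[i], "'", call. = FALSE)
    }
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!(key %in% names(.CONFIG_KEYS))) {
      stop("invalid configuration: unknown field '", key, "'", call. = FALSE)
    }
    arg <- .CONFIG_KEYS[[key]]
    if (key == "class_proportions") {
      pairs <- strsplit(strsplit(val, ",", fixed = TRUE)[[1L]], ":",
                        fixed = TRUE)
      p <- vapply(pairs, function(x) as.numeric(x[2L]), numeric(1))
      names(p) <- vapply(pairs, `[`, character(1), 1L)
      args[[arg]] <- p
    } else {
      args[[arg]] <- as.numeric(val)
    }
  }
  do.call(CohortConfig, args)
}
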