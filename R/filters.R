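## The six-rule hard-filter cascade and per-scenario pass-rate accounting.

.RULES <- c("depth", "alt_support", "gap", "qual", "indel", "aaf")

#' Apply the six-rule variant filter cascade
#'
#' A record passes iff, in this order: site read depth >= `minDepth`; total
#' alternative-supporting reads >= `minAltReads`; the site is not flagged
#' near a gap; Phred site quality >= `minQual`; the site is not flagged near
#' an INDEL; and the read-based site alternative allele frequency (total alt
#' reads over total reads) >= `minAAF`. Removals are attributed to the first
#' failing rule; because the predicate is a conjunction, the set of
#' survivors does not depend on rule order. Input record order is preserved.
#'
#' @param calls a [CallSet].
#' @param config a [FilterConfig] (defaults: 10 reads, 2 alt reads, 3 bp gap
#'   window, QUAL 30, 5 bp INDEL window, 20% AAF).
#' @return a list with `calls` (the filtered [CallSet]) and `report` (a
#'   one-row data.frame: `label`, `n_before`, `n_after`, `pct_pass` to two
#'   decimals, and per-rule removal counts `removed_depth`,
#'   `removed_alt_support`, `removed_gap`, `removed_qual`, `removed_indel`,
#'   `removed_aaf`). For an empty call set `pct_pass` is defined as 0.00
#'   (with a warning).
#' @seealso [passRateSummary()], [filterReport()]
#' @examples
#' cohort <- simulateCohort(CohortConfig(nSites = 100, seed = 2))
#' sch <- buildScheme(cohortSamples(cohort), "MERGED_BY_GROUP")
#' calls <- callVariants(cohortPileups(cohort), sch, label = "iii")
#' applyFilters(calls, FilterConfig())$report
#' @export
applyFilters <- function(calls, config = FilterConfig()) {
  validObject(config)
  if (!is(calls, "CallSet")) {
    stop("'calls' must be a CallSet", call. = FALSE)
  }
  n <- nVariants(calls)
  if (n == 0L) {
    warning("empty CallSet: pct_pass defined as 0.00")
    report <- data.frame(label = callLabel(calls), n_before = 0L,
                         n_after = 0L, pct_pass = 0)
    for (r in .RULES) report[[paste0("removed_", r)]] <- 0L
    return(list(calls = calls, report = report))
  }
  dp <- siteDepth(calls)
  alt <- altReads(calls)
  total <- dp
  aaf <- ifelse(total > 0, alt / total, 0)
  rd <- calls@rowdata
  failures <- cbind(
    depth = dp < config@minDepth,
    alt_support = alt < config@minAltReads,
    gap = rd$nearGap,
    qual = rd$qual < config@minQual,
    indel = rd$nearIndel,
    aaf = aaf < config@minAAF)
  firstFail <- apply(failures, 1L, function(f) {
    w <- which(f)
    if (length(w)) w[1L] else 0L
  })
  keep <- firstFail == 0L
  removed <- tabulate(firstFail, nbins = length(.RULES))
  report <- data.frame(label = callLabel(calls), n_before = n,
                       n_after = sum(keep),
                       pct_pass = roundHalfUp(100 * sum(keep) / n, 2))
  for (i in seq_along(.RULES)) {
    report[[paste0("removed_", .RULES[i])]] <- removed[i]
  }
  list(calls = calls[keep], report = report)
}

#' Build a filter report row from before/after counts
#'
#' Constructs the same one-row summary [applyFilters()] produces, directly
#' from a scenario label and its before/after record counts — useful for
#' pass-rate arithmetic over externally reported filtering results.
#' `pct_pass` is `100 * n_after / n_before` rounded half away from zero to
#' two decimals (0.00 if `n_before` is 0).
#'
#' @param label scenario name.
#' @param nBefore,nAfter record counts before and after filtering.
#' @return a one-row data.frame `label`, `n_before`, `n_after`, `pct_pass`.
#' @examples
#' filterReport("liver_i", 626460, 258120)$pct_pass   # 41.20
#' @export
filterReport <- function(label, nBefore, nAfter) {
  if (nAfter > nBefore || nBefore < 0 || nAfter < 0) {
    stop("need 0 <= n_after <= n_before", call. = FALSE)
  }
  pct <- if (nBefore == 0) 0 else roundHalfUp(100 * nAfter / nBefore, 2)
  data.frame(label = label, n_before = nBefore, n_after = nAfter,
             pct_pass = pct, stringsAsFactors = FALSE)
}

#' Mean and SD of filter pass rates across scenarios
#'
#' Summarizes the percentage of records passing all filters over a set of
#' filter reports, as mean and sample standard deviation (n - 1 denominator;
#' 0 for a single report), each rounded half away from zero to two decimals.
#'
#' @param reports a data.frame of report rows (e.g. `rbind` of
#'   [filterReport()] / `applyFilters()$report` rows) or a list of them.
#' @return a list with `pct_pass` (per-scenario vector), `mean` and `sd`.
#' @examples
#' reps <- rbind(filterReport("a", 200, 100), filterReport("b", 100, 30))
#' passRateSummary(reps)
#' @export
passRateSummary <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, lapply(reports, function(r) {
      r[, c("label", "n_before", "n_after", "pct_pass"), drop = FALSE]
    }))
  }
  if (is.null(reports) || nrow(reports) == 0L) {
    stop("no filter reports supplied", call. = FALSE)
  }
  if (any(reports$n_before <= 0)) {
    stop("all reports must have n_before > 0", call. = FALSE)
  }
  pct <- reports$pct_pass
  list(pct_pass = stats::setNames(pct, reports$label),
       mean = roundHalfUp(mean(pct), 2),
       sd = roundHalfUp(.sampleSD(pct), 2))
}
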