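## One-call orchestration of the full comparison: simulate -> call under the
## three approaches -> filter -> compare -> contrast -> summarize.

#' Key-union of two call sets
#'
#' Combines two call sets by variant key: all records of `a`, plus the
#' records of `b` whose key is absent from `a`. Used to form the combined
#' liver-and-muscle scenarios for the per-tissue approaches. Genotype
#' columns are not merged — the union is a set-level object whose records
#' retain their originating genotypes — so only key-level and site-level
#' statistics (counts, QUAL, depth) are meaningful on it.
#'
#' @param a,b [CallSet] objects.
#' @param label label for the union.
#' @return a [CallSet] (genotype columns follow `a` for records from `a`
#'   and `b` for the rest; the two blocks are padded with missing genotypes
#'   if the column sets differ).
#' @export
unionCallSets <- function(a, b, label = paste0(callLabel(a), "+",
                                               callLabel(b))) {
  extra <- !(variantKeys(b) %in% variantKeys(a))
  bx <- b[extra]
  allIds <- union(genotypeNames(a), genotypeNames(b))
  pad <- function(x) {
    add <- setdiff(allIds, genotypeNames(x))
    n <- nVariants(x)
    grow <- function(m, fill) {
      extraM <- matrix(fill, nrow = n, ncol = length(add),
                       dimnames = list(NULL, add))
      cbind(m, extraM)[, allIds, drop = FALSE]
    }
    CallSet(rowdata = x@rowdata, gt = grow(x@gt, "./."),
            adRef = grow(x@adRef, 0L), adAlt = grow(x@adAlt, 0L),
            dp = grow(x@dp, 0L), label = label)
  }
  a <- pad(a); bx <- pad(bx)
  CallSet(rowdata = rbind(a@rowdata, bx@rowdata),
          gt = rbind(a@gt, bx@gt), adRef = rbind(a@adRef, bx@adRef),
          adAlt = rbind(a@adAlt, bx@adAlt), dp = rbind(a@dp, bx@dp),
          label = label)
}

.SCENARIOS <- data.frame(
  label = c("i_liver", "i_muscle", "ii_liver", "ii_muscle", "iii"),
  approach = c("NON_MERGED", "NON_MERGED", "MERGED_BY_GROUP_TISSUE",
               "MERGED_BY_GROUP_TISSUE", "MERGED_BY_GROUP"),
  tissue = c("LIVER", "MUSCLE", "LIVER", "MUSCLE", NA),
  stringsAsFactors = FALSE)

#' Run the full merging-strategy comparison experiment
#'
#' Simulates a cohort, calls variants under the three merging approaches
#' (per tissue for approaches i and ii, plus combined liver-and-muscle
#' scenarios formed as key-unions of the per-tissue call sets), applies the
#' filter cascade, and computes the whole comparison battery:
#' per-scenario filter reports, the four canonical pairwise set partitions
#' (i vs ii per tissue; combined i vs iii; combined ii vs iii), per-scenario
#' depth summaries, the Cohen's d matrix on site quality, allele-frequency
#' sharing curves of every other scenario against approach iii, the
#' fixed-within-group partition of the filtered approach-iii call set, and
#' truth-based sensitivity (per scenario and variant class) with the
#' false-site rate among invariant truth sites as specificity complement.
#'
#' The set partitions, depth summaries, quality effect sizes and sharing
#' curves are computed on the called (pre-filter) sets: under exactly
#' additive pooling every filter predicate is identical across approaches
#' at a given site, so post-filter call sets coincide across approaches and
#' a post-filter comparison would be degenerate — the between-approach
#' differences (rare-variant dilution in pools, per-sample error-site
#' emission) are expressed at the calling stage. The filter reports and the
#' fixed-within-group partition use the filtered sets.
#'
#' @param config a [CohortConfig].
#' @param filterConfig a [FilterConfig].
#' @param outDir optional directory; if given, per-scenario unfiltered and
#'   filtered VCFs, all summary TSVs, the truth table, and a JSON run
#'   manifest are written there.
#' @param binWidth bin width for the sharing curves.
#' @param callerErrorRate error rate used by the caller (may differ from
#'   the generator's; must be in (0, 0.5)).
#' @return a list bundle: `cohort`, `scenarios` (per label: `calls`,
#'   `filtered`, `report`), `filterReports`, `passRates`, `comparisons`,
#'   `depthSummaries`, `cohensD` (matrix), `aafCurves`, `partition`,
#'   `accuracy`.
#' @examples
#' bundle <- runExperiment(CohortConfig(nSites = 100, seed = 11))
#' bundle$filterReports
#' @export
runExperiment <- function(config = CohortConfig(),
                          filterConfig = FilterConfig(),
                          outDir = NULL, binWidth = 0.1,
                          callerErrorRate = 0.01) {
  cohort <- simulateCohort(config)
  samples <- cohortSamples(cohort)
  pileups <- cohortPileups(cohort)

  scen <- list()
  for (i in seq_len(nrow(.SCENARIOS))) {
    lab <- .SCENARIOS$label[i]
    tissue <- .SCENARIOS$tissue[i]
    sch <- buildScheme(samples, .SCENARIOS$approach[i],
                       tissue = if (is.na(tissue)) NULL else tissue)
    calls <- callVariants(pileups, sch, errorRate = callerErrorRate,
                          label = lab)
    flt <- applyFilters(calls, filterConfig)
    scen[[lab]] <- list(calls = calls, filtered = flt$calls,
                        report = flt$report)
  }
  for (u in list(c("i_liver", "i_muscle", "i_both"),
                 c("ii_liver", "ii_muscle", "ii_both"))) {
    calls <- unionCallSets(scen[[u[1L]]]$calls, scen[[u[2L]]]$calls,
                           label = u[3L])
    filtered <- unionCallSets(scen[[u[1L]]]$filtered,
                              scen[[u[2L]]]$filtered, label = u[3L])
    scen[[u[3L]]] <- list(calls = calls, filtered = filtered,
                          report = filterReport(u[3L], nVariants(calls),
                                                nVariants(filtered)))
  }
  order7 <- c("i_liver", "i_muscle", "i_both", "ii_liver", "ii_muscle",
              "ii_both", "iii")
  scen <- scen[order7]

  reports <- do.call(rbind, lapply(scen, function(s) {
    s$report[, c("label", "n_before", "n_after", "pct_pass")]
  }))
  rownames(reports) <- NULL
  passRates <- passRateSummary(reports)

  pairs <- list(c("i_liver", "ii_liver"), c("i_muscle", "ii_muscle"),
                c("i_both", "iii"), c("ii_both", "iii"))
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    partitionVariants(scen[[p[1L]]]$calls, scen[[p[2L]]]$calls)
  }))

  depthSummaries <- do.call(rbind, lapply(order7, function(lab) {
    cbind(label = lab, depthSummary(scen[[lab]]$calls))
  }))
  rownames(depthSummaries) <- NULL

  cohensD <- matrix(0, length(order7), length(order7),
                    dimnames = list(order7, order7))
  for (i in seq_along(order7)) {
    for (j in seq_along(order7)) {
      if (i < j) {
        d <- cohensDQual(scen[[order7[i]]]$calls, scen[[order7[j]]]$calls)
        cohensD[i, j] <- d
        cohensD[j, i] <- d
      }
    }
  }

  curveRefs <- setdiff(order7, "iii")
  aafCurves <- lapply(scen[curveRefs], function(s) {
    aafSharingCurve(s$calls, scen$iii$calls, binWidth = binWidth)
  })

  partition <- identifyFixedVariants(scen$iii$filtered)

  truth <- cohortTruth(cohort)
  truthKey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  accuracy <- do.call(rbind, lapply(order7, function(lab) {
    keys <- variantKeys(scen[[lab]]$filtered)
    do.call(rbind, lapply(VARIANT_CLASSES, function(cl) {
      clKeys <- truthKey[truth$class == cl]
      nDet <- sum(clKeys %in% keys)
      data.frame(label = lab, class = cl, n_truth = length(clKeys),
                 n_detected = nDet,
                 rate = if (length(clKeys)) nDet / length(clKeys) else NA,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(accuracy) <- NULL

  bundle <- list(cohort = cohort, scenarios = scen,
                 filterReports = reports, passRates = passRates,
                 comparisons = comparisons,
                 depthSummaries = depthSummaries, cohensD = cohensD,
                 aafCurves = aafCurves, partition = partition,
                 accuracy = accuracy, config = config,
                 filterConfig = filterConfig)
  if (!is.null(outDir)) .writeBundle(bundle, outDir, callerErrorRate,
                                     binWidth)
  bundle
}

.writeBundle <- function(bundle, outDir, callerErrorRate, binWidth) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  tsv <- function(d, f) {
    utils::write.table(d, file.path(outDir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (lab in names(bundle$scenarios)) {
    writeVcfCalls(bundle$scenarios[[lab]]$calls,
                  file.path(outDir, paste0(lab, ".vcf")))
    writeVcfCalls(bundle$scenarios[[lab]]$filtered,
                  file.path(outDir, paste0(lab, ".filtered.vcf")))
  }
  tsv(bundle$filterReports, "filter_reports.tsv")
  tsv(bundle$comparisons, "comparisons.tsv")
  tsv(bundle$depthSummaries, "depth_summaries.tsv")
  utils::write.table(bundle$cohensD, file.path(outDir, "cohens_d.tsv"),
                     sep = "\t", quote = FALSE)
  for (lab in names(bundle$aafCurves)) {
    tsv(bundle$aafCurves[[lab]], paste0("aaf_curve_", lab, ".tsv"))
  }
  ct <- partitionCounts(bundle$partition)
  tsv(data.frame(set = names(ct), n = as.integer(ct)),
      "group_partition.tsv")
  iiiF <- bundle$scenarios$iii$filtered
  keys <- variantKeys(iiiF)
  writeVcfCalls(iiiF[keys %in% uniqueLow(bundle$partition)],
                file.path(outDir, "unique_low.vcf"))
  writeVcfCalls(iiiF[keys %in% uniqueHigh(bundle$partition)],
                file.path(outDir, "unique_high.vcf"))
  writeVcfCalls(iiiF[keys %in% sharedKeys(bundle$partition)],
                file.path(outDir, "shared.vcf"))
  tsv(bundle$accuracy, "accuracy.tsv")
  writeTruth(cohortTruth(bundle$cohort), file.path(outDir, "truth.tsv"))
  cfg <- bundle$config
  manifest <- list(
    package = "MergeCall",
    version = as.character(utils::packageVersion("MergeCall")),
    r_version = as.character(getRversion()),
    seed = cfg@seed,
    caller_error_rate = callerErrorRate,
    aaf_bin_width = binWidth,
    cohort_config = list(
      n_per_group_per_tissue = cfg@nPerGroupPerTissue,
      n_sites = cfg@nSites, mean_depth_liver = cfg@meanDepthLiver,
      muscle_depth_ratio = cfg@muscleDepthRatio,
      expression_dispersion = cfg@expressionDispersion,
      error_rate = cfg@errorRate,
      class_proportions = as.list(cfg@classProportions),
      gap_fraction = cfg@gapFraction, indel_fraction = cfg@indelFraction,
      n_genes = cfg@nGenes),
    filter_config = list(
      min_depth = bundle$filterConfig@minDepth,
      min_alt_reads = bundle$filterConfig@minAltReads,
      gap_window = bundle$filterConfig@gapWindow,
      min_qual = bundle$filterConfig@minQual,
      indel_window = bundle$filterConfig@indelWindow,
      min_aaf = bundle$filterConfig@minAAF))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
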