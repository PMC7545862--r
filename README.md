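# MergeCall

Comparing RNA-seq sample-merging strategies for SNP detection.

## The problem

SNP discovery from RNA-seq alignments of a structured cohort — for example
cattle divergent for feed efficiency (low vs high residual feed intake,
RFI), each animal sampled in liver and muscle — can present the data to a
joint genotype caller in three ways: **i)** every sample as its own
genotype, **ii)** samples merged by group within each tissue, or
**iii)** samples merged by group across tissues. Merging raises read depth
per site and lets marginal variants clear depth filters, but a pool is
genotyped as a single diploid, so a low-frequency allele can be *diluted*
below detectability (the pooled allele fraction approaches the
sequencing-error rate), while per-sample calling *inflates* Phred site
quality for variants carried by many samples. Which strategy wins depends
on the variant-frequency structure of the cohort.

MergeCall makes the trade-off reproducible at desk scale, for
bioinformaticians designing multi-sample RNA-seq variant pipelines: a
synthetic pileup cohort generator with known per-site truth, additive
count pooling, a simplified multi-sample genotype-likelihood caller that
exhibits both failure modes, the six-rule filter cascade used by such
pipelines, and the full comparison battery (set partitions, depth
summaries, quality effect sizes, allele-frequency sharing curves,
fixed-within-group SNP identification, gene assignment, and
hypergeometric gene-set enrichment).

## The model in brief

For a genotype with `r` reference and `a` alternative reads, the
likelihood of diploid dosage `g ∈ {0,1,2}` is `Binomial(a; r+a, p_g)` with
`p_g = (g/2)(1−ε) + (1−g/2)ε` at per-read error rate `ε`. With a flat
prior, the Phred site quality over genotype columns `s` is

    QUAL = −10 Σ_s log10 P(g_s = 0 | r_s, a_s)

(informative genotypes only, capped at 10,000), and a record is emitted
when `QUAL ≥ 3.0103` and at least one alternative read exists. Filters:
site DP ≥ 10, alt reads ≥ 2, no gap within 3 bp, QUAL ≥ 30, no INDEL
within 5 bp, site AAF ≥ 20%. See the methods vignette
(`vignettes/merging-strategies.Rmd`) for assumptions and design choices.

## Worked example

```r
library(MergeCall)
bundle <- runExperiment(CohortConfig(seed = 42))

bundle$filterReports
#>       label n_before n_after pct_pass
#> 1   i_liver      775     563    72.65
#> 2  i_muscle      749     554    73.97
#> 3    i_both      853     580    68.00
#> 4  ii_liver      645     563    87.29
#> 5 ii_muscle      648     554    85.49
#> 6   ii_both      654     580    88.69
#> 7       iii      647     567    87.64

bundle$comparisons[, c("label_a", "label_b", "pct_unique_a",
                       "pct_shared", "pct_unique_b")]
#>    label_a   label_b pct_unique_a pct_shared pct_unique_b
#> 1  i_liver  ii_liver        16.77      83.23            0
#> 2 i_muscle ii_muscle        13.48      86.52            0
#> 3   i_both       iii        24.15      75.85            0
#> 4  ii_both       iii         1.07      98.93            0

bundle$depthSummaries[, c("label", "median", "mean", "sd")]
#>       label median     mean        sd
#> 1   i_liver    102 115.6929  60.02948
#> ...
#> 7       iii    348 388.2488 198.40007

partitionCounts(bundle$partition)
#>  unique_low unique_high      shared       total
#>          52          56         459         567
```

Reading the output: the non-merged scenarios call the most sites before
filtering (775 + 749 per tissue vs 647 for approach iii) because each
sample's reads can individually support rare singletons and error-driven
candidates; a quarter of the combined non-merged call set (24.15%) is
invisible to the fully merged approach — dilution — while the two merged
strategies nearly coincide (98.93% shared). Approach iii has the deepest
per-variant coverage (mean 388 vs 116 reads for non-merged liver), the
depth advantage that rescues threshold-straddling variants. The group
partition splits the filtered two-genotype approach-iii call set into
variants fixed within the low-RFI group, fixed within the high-RFI group,
and shared.

The deterministic dilution example, at the prompt:

```r
callSite(0, 10, errorRate = 0.01)          # hom-alt sample: QUAL 199.6, emitted
callSite(55, 5, errorRate = 0.01)          # same 5 alt reads pooled 6-fold: NULL
```

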