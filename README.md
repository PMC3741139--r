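# mmrsig

Expression signatures discriminating hereditary colorectal cancer by
mismatch-repair (MMR) status.

Hereditary colorectal cancer in the HNPCC spectrum splits into **Lynch
syndrome** (germline mismatch-repair mutations; tumors MMR-deficient) and
**FCCTX** (familial colorectal cancer type X; Amsterdam-criteria families
with retained MMR function). Although the two present with similar family
histories, their tumors carry different expression programs, dominated by
MMR status. `mmrsig` implements the full computational chain for deriving
such a signature and transferring it to independent cohorts:

- **Preprocessing** — detection-p-value feature filtering (keep genes with
  p ≤ 0.01 in ≥ 80% of samples), cubic-spline normalization against a
  mean-quantile reference, plate scaling, log2 transform with per-gene
  median centering.
- **Differential expression** — a from-scratch two-class SAM (Significance
  Analysis of Microarrays): relative-difference score
  `d = (mean2 − mean1) / (s + s0)` with pooled standard error `s` and fudge
  factor `s0`, a label-permutation null (exhaustive when feasible), and a
  delta threshold chosen on the observed-vs-expected quantile plot so the
  permutation-estimated FDR stays at or below 5%.
- **Clustering** — UPGMA (average linkage) on Pearson-correlation distance
  `1 − r`, deterministic tie-breaking, two-major-cluster cut scored against
  MMR status.
- **Classification** — per-class mean centroids over the signature genes;
  external samples are assigned by maximum Pearson correlation to a
  centroid, after a fixed RPKM harmonization recipe (quantile normalize,
  +32 offset capped at 65,000, log2, gene median centering, batch-mean
  adjustment, drop the 50% least-varying genes).
- **Clinical statistics** — Fisher's exact tests on 2×2 contrasts, with
  counts reconstructed from printed group percentages.
- **Synthetic cohorts** — a seeded generator producing the four-subtype
  study design (39 Lynch / 37 FCCTX / 26 sporadic MMR-deficient / 21
  sporadic MMR-proficient), planted MMR and subtype effects, plate effects,
  intensity-dependent detection p-values, and an RPKM-scale external cohort
  with batch structure — with ground truth, so signature recovery is
  testable.

Everything is tidyverse-native: expression cohorts are tibbles
(`gene_id` column + one numeric column per sample), fitted objects have
`tidy()`, `glance()` and `autoplot()` methods, and stages compose with the
pipe.

## Worked example

```r
library(mmrsig)

cfg <- pipeline_config(
  output_dir = "mmrsig-run",
  seed       = 1,
  synthetic  = synthetic_config(),          # 2,000 genes, 123-sample cohort
  sam        = sam_config(n_permutations = 200)
)
res <- run_pipeline(cfg)

res$sam_subtype
#> Two-class SAM fit: FCCTX vs LYNCH (37 + 39 samples)
#>   s0 = 0.1852, delta = 0.587, pi0 = 1.000
#>   298 genes called at estimated FDR 0.0343 (target 0.05), 200 permutations

res$summary$cluster_mmr_agreement
#> [1] 1

res$report
#> Nearest-centroid classification by MMR status
#>   MMR deficient  -> LYNCH: 30/30 (100%)
#>   MMR proficient -> FCCTX: 30/30 (100%)
#>   signature overlap used: 86%
```

Reading the output: SAM called a 298-gene Lynch-vs-FCCTX signature at an
estimated FDR of 3.4% (the run summary also reports recovery against the
planted truth — here sensitivity 1.00 at realized FDR 0.037); unsupervised
clustering of all 123 tumors splits them perfectly along MMR status; and
centroids trained on the hereditary subset classify every sample of the
harmonized external RPKM cohort into the MMR-matched class, using the 86% of
signature genes that survive the external variance filter.

Clinical contrasts work from printed percentages:

```r
fisher_from_percentages(39, c(77, 23), 37, c(5, 95))   # tumor location
#>   group  category1 category2  p_value
#> 1 group1        30         9  5.61e-11
#> 2 group2         2        35  5.61e-11
```

Every artifact (matrices, signatures, dendrogram, centroid model,
classification report, run summary with seeds, parameters and MD5 hashes) is
written as TSV/JSON under `output_dir`; the same config and seed reproduce
them byte for byte.

## Package tour

| Area | Functions |
| --- | --- |
| I/O | `read_expression()`, `read_annotation()`, `read_gene_list()` + writers |
| Simulation | `synthetic_config()`, `simulate_cohort()`, `simulate_external_cohort()`, `simulate_clinical()` |
| Preprocess | `filter_detection()`, `normalize_qspline()`, `scale_plates()`, `log2_median_center()`, `preprocess_cohort()` |
| Harmonize | `normalize_quantiles()`, `offset_and_cap()`, `center_genes()`, `adjust_batch_means()`, `filter_variance()`, `harmonize_external()` |
| SAM | `sam_config()`, `sam_two_class()`, `sam_d_scores()`, `sam_estimate_s0()`, `sam_permutation_null()`, `sam_select_delta()`, `significant_genes()` |
| Clustering | `pearson_distance()`, `upgma()`, `cut_two()`, `cluster_agreement()` |
| Classifier | `build_centroids()`, `classify_samples()`, `evaluate_by_mmr()` |
| Stats | `fisher_exact_2x2()`, `counts_from_percentages()`, `fisher_from_percentages()` |
| Pipeline | `pipeline_config()`, `run_pipeline()` (CLI wrapper in `inst/scripts/run-pipeline.R`) |

The methods vignette (`vignettes/mmr-signature-methods.Rmd`) documents the
model, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and the package's numerical
choices.
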