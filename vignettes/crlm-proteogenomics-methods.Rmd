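---
title: "Methods: proteogenomic analysis of paired N/T/LM cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic analysis of paired N/T/LM cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crlmomics` implements the downstream analysis of a TMT proteogenomic study
of colorectal cancer liver metastasis (CRLM): paired adjacent-normal (N),
primary tumor (T) and liver metastasis (LM) tissues per patient, profiled
for gene-level copy number (SCNA), mRNA, protein and phosphosite abundance.
Upstream processing — variant calling, SCNA segmentation, MS database search
and TMT reporter quantification, rMATS splicing quantification, kinase-
substrate prediction, phosphosite functional-score modeling — is out of
scope; their outputs are consumed as plain tabular inputs. All numbered
steps under `analysis/` are thin drivers over the package functions that
the test suite and `scripts/acceptance.R` exercise directly.

# Statistical core

Group comparisons use the two-sided Wilcoxon tests: **signed-rank on
per-patient differences** for paired tissue contrasts (LM vs T within a
patient), **rank-sum** for unpaired contrasts (subtype C1 vs C2). The
figure-legend conventions in this field pair these tests with fold-change
filters on raw p;
the package applies exact enumeration whenever the smaller group has at
most 8 observations (15 nonzero differences for the signed-rank test) and
the data are tie-free, otherwise the tie-corrected normal approximation
with 0.5 continuity correction. Each result records which branch ran.

"FDR" is implemented as Benjamini–Hochberg throughout; the field default
when no procedure is named. Over-representation uses the one-sided
hypergeometric test against the **quantified-feature universe** rather than
the genome, avoiding detection bias. Spearman correlations use average
ranks for ties and a t-approximation on n − 2 degrees of freedom for the
p-value; a constant margin yields a flagged missing correlation, never
zero. Survival uses the Kaplan–Meier product-limit estimator and the
log-rank test with hypergeometric variance at tied event times (via the
`survival` package); "correlated with prognosis" is operationalized as a
median split of the per-sample quantity (ties to the low stratum); the
median is the parameter-free choice when no split is otherwise specified.

# Pipeline stages and their tunable parameters

* **Normalization** (`normalize_log2_median`): log2 then per-sample median
  subtraction over non-missing values; idempotent via the
  `is_normalized` flag. Missingness is encoded as NA; zeros are data.
* **Missingness filter**: keep features with missing fraction strictly
  below the threshold (default 0.10 in the biomarker cascades).
* **Variance filter** (`mad_select`): raw MAD (no 1.4826 constant) on log2
  values, strict `> 1` by default — the bare threshold convention of
  "most variant proteins (MAD > 1)". Computed on the analysis cohort after
  sample filtering.
* **Cis-effect scan** (`cis_correlation_scan`): per-gene Spearman of CNV
  against each layer within a tissue subset, `min_pairs = 10`
  (10 complete pairs is about the smallest n at which the t-approximation
  is usable), BH within layer. Phosphosites are
  aggregated per gene by the most significant site, with per-site records
  retained.
* **Differential testing** (`differential_table`): features need ≥ 3
  non-missing values per group; log2 fold change is the difference of
  group means of log2 values, the estimator consistent with median
  normalization. Default layer filters:
  mrna FC > 1.5, protein FC > 1.2, phosphosite FC > 1.5, all raw p < 0.05,
  strict inequalities; q is reported alongside.
* **Signature construction** (`build_enriched_sets`): enriched-set
  construction criteria vary between studies, so every criterion here is a
  declared, logged parameter; the defaults are paired signed-rank LM vs T with q < 0.05,
  |FC| > 1.5, detection in ≥ 50% of pairs, direction defining LM-/T-
  membership, and an optional tissue-specific exclusion list. All
  parameters are recorded in the returned object.
* **Preranked GSEA** (`preranked_gsea`): weighted-KS running sum
  (weight 1), gene-label permutations (seed mandatory), NES normalized
  separately for positive/negative ES, GSEA-convention FDR on pooled
  permutation NES. The default ranking metric is the signed log2 fold
  change; a test-statistic-based alternative is one argument away.
* **KSEA** (`ksea_scores`): classical substrate-set
  z = (mean~substrates~ − mean~background~)·√m / sd~background~ with the
  full quantified-site contrast distribution as background;
  `min_substrates = 3`. Paired contrasts (median per-patient difference)
  for tissue comparisons, group-mean differences for subtype comparisons,
  matching the pairing structure of each figure-level contrast.
* **Consensus clustering** (`consensus_cluster`): 250 iterations of 80%
  sample subsampling, per-subsample feature z-scoring, k-means (Euclidean,
  10 restarts); consensus = co-cluster frequency among co-sampled pairs;
  final labels by average-linkage cut of 1 − consensus; k by maximum
  delta-area of the consensus CDF with PAC reported, overridable. These
  are the common defaults of the consensus-clustering literature and are
  all logged in the result.
  Cluster naming: the cluster with the higher median metabolism-set score
  is C1.
* **Splicing** (`filter_as_events`, `as_survival_scan`,
  `factor_event_network`): rMATS-style tables filtered at FDR < 0.05 and
  |ΔPSI| > 0.1 (strict); per-event median-PSI survival splits (OS is the
  default endpoint); factor–event Spearman network with BH across the full
  factor × event grid (not per factor; the grid-wide correction is the
  conservative choice).
* **Biomarker cascades** (`protein_biomarker_scan`,
  `phospho_biomarker_scan`): stages as printed — missingness < 10%;
  C1-LM higher than each of the five other sample sets at FC > 1.2,
  p < 0.05 (proteins) or C1 vs C2 |FC| > 1.5, p < 0.05 (phosphosites);
  functional score > 0.5 (phosphosites); median-split log-rank p < 0.05 in
  LM samples. N samples inherit their patient's LM subtype, which is what
  grouping normal samples by subtype implies. Stage-2 comparisons are
  unpaired rank-sum by default (a paired option exists for the
  C1-LM vs C1-T leg). Every candidate's full stage trace is retained, and
  the failing stage is named.

# The synthetic cohort and what it does (not) emulate

`generate_cohort` plants a fully recoverable truth. Defaults mirror the
study's shape: 34 patients × (N, T, LM) = 102 samples, 8000 genes,
~2 phosphosites/gene, ~15% missingness in the MS layers, three IRS
replicate columns.

* **Cis-effect chain**: per-patient gene copy states ∈ {−1, 0, +1}
  (P = 0.3/0.4/0.3), then mrna = a·cnv + tissue effect + N(0, 1),
  protein = b·mrna + N(0, 1), phosphosite = protein + N(0, σ~s~). The
  coefficients a, b, σ~s~ are solved in closed form so the cnv–layer
  correlations hit the configured targets (0.6, 0.4, 0.25) in expectation;
  a target ordering that the chain cannot produce raises an explicit
  error. Normal tissue is copy-neutral.
* **Tissue effects**: 245 LM-enriched and 96 T-enriched genes shifted by
  2.8 log2 units at the mRNA level (~2.0 at protein after chain
  attenuation). The size is the package's choice, set so that the planted sets are recoverable by the
  signature-construction defaults in the presence of 15% intensity-
  dependent missingness, which shrinks observed fold changes of
  low-abundance features.
* **Subtypes**: balanced C1/C2 prevalence per cohort; 300 metabolism-block
  genes shifted +2.6 log2 in C1 LM samples, 300 RNA-function-block genes
  in C2 LM samples (≈ 2 marginal protein SDs). Survival is exponential
  with log-hazard log(3)·1[C1] around a 3-year C2 median, with independent
  exponential censoring (~30%).
* **Kinases**: 5 active kinases × 15 substrate sites shifted +1 log2 in LM
  samples, 15 inactive kinases padding the substrate map.
* **Biomarkers**: 10 protein markers shifted +1.5 log2 in C1-LM only, and
  10 phosphosites shifted +1.2 in C1 LM samples with functional scores in
  (0.6, 0.95). Markers are modeled as abundant, protein-level effects:
  their residual noise is 0.5 (TMT noise is intensity-dependent) and they
  are decoupled from their transcripts, the behavior of post-
  transcriptionally regulated markers.
* **Missingness**: MCAR (2%) plus a logistic MNAR component in log2
  abundance calibrated to ~13%, applied after the planted effects so fold
  changes stay interpretable.
* **Splicing**: 60 events; 15 with a subtype-dependent PSI logit shift,
  11 driven (positively or negatively) by one of 6 splicing-factor
  proteins; `IncLevelDifference` and FDR columns are computed from the
  generated PSI exactly as an rMATS consumer would see them.
* **Determinism**: one global seed feeds an independent, key-derived
  substream per component, so enabling or resizing one layer never
  perturbs another layer's draws; identical configs yield byte-identical
  outputs.

Not emulated: raw spectra, TMT ratio compression, batch/plex structure
beyond the IRS columns, mutation hotspots, segment-level SCNA, biological
pathway correlation structure. Passing recovery tests therefore
demonstrates the pipeline's correctness and calibration, not that real
CRLM data would yield these effect sizes.

# Numerical choices and problem sizes

Matrices are serialized with 17 significant digits so write→read round
trips are bit-exact; normalized files carry a `#scale=log2` header. PCA
signs follow the largest-loading-positive convention, making ordinations
reproducible. Test and acceptance cohorts are scaled by design: recovery
rates use 400–2000-gene cohorts (the statistics are per-feature, so gene
count affects only multiplicity, which the scenarios preserve
proportionally), the subtype-recovery scenario uses 40 patients with the
spec-shaped 300-gene block, the biomarker-cascade scenario uses 120
patients so that the survival stage has ~98% power and recovery measures
the cascade rather than log-rank sampling noise, and the KSEA recovery
scenario disables missingness because MNAR induces an abundance-dependent
per-kinase contrast bias that deliberately remains active everywhere else.
The end-to-end determinism check runs a reduced 16-patient/900-gene
configuration twice and compares artifact checksums; determinism does not
depend on problem size.

# Known limitations

* The cis-effect targets are calibrated for Pearson correlation of the
  generating chain; observed Spearman values run ~3–5% lower (rank
  attenuation on a 3-level copy-number variable).
* Per-gene power at the default effect sizes is ~0.85 for cis detection
  after BH, so planted-cis recall around 0.8–0.9 is expected behavior,
  not a defect.
* The consensus-clustering k-selection (delta-area) is a heuristic;
  the package reports PAC and per-k consensus so a user can override k.
* `median_split_survival` refuses degenerate splits (all-equal scores)
  rather than guessing strata.
* The GSEA FDR follows the permutation convention and is conservative for
  collections of very few sets; the nominal permutation p is reported
  alongside.
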