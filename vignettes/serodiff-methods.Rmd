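---
title: "Methods: cross-validated differential abundance in serum proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-validated differential abundance in serum proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serodiff)
```

## The problem

Cholangiocarcinoma (CCA) and benign biliary tract diseases (BBTD) present
with near-identical clinical symptoms, and the routine serum markers (CEA,
CA19-9) do not separate them reliably. Label-free LC-MS/MS quantitation of
whole serum yields a protein-by-sample matrix of relative abundance ratios
from which candidate discriminating proteins can be mined. `serodiff`
implements that mining pipeline for a two-group case/control design:
normalization, a cross-validated Welch-test selection rule, unsupervised
validation views, and cohort-level clinical statistics — together with a
synthetic-data generator so the whole chain is testable without patient
data.

## The selection procedure

Values are analyzed on the log2 scale. Each sample is median-centred
(subtracting its median over observed values), then rank-normalized across
the data set: within each sample the observed values are ranked (ties
averaged) and replaced by the cross-sample mean value at that rank, so all
sample distributions coincide. We read "rank normalization across the data
set" as cross-sample quantile normalization — the standard device for making
label-free samples comparable — and back it with
`limma::normalizeQuantiles(ties = TRUE)`, which also handles unequal numbers
of observed values per sample by linear interpolation of the reference
profile. A per-protein rank transform is available as an alternative
(`rank_normalize(method = "protein_rank")`) but is not the default, because
it discards the shared abundance scale that the downstream fold-change
estimates need.

The cohort is split into k = 6 stratified train/validation folds. At the
reference size (17 BBTD + 19 CCA) every training set holds 30 samples with
13–15 BBTD and 15–17 CCA, every validation set 6 samples with 2–4 of each
group; for other cohort sizes the per-group validation counts must fall in
`round(n_group/k) ± 1`, which reduces to exactly those bounds at 36 samples.
Two constructions are offered. *Partition* mode (default) makes the six
validation sets disjoint and covering — the conventional meaning of k-fold
cross-validation. *Resample* mode draws each fold's split independently,
which the looser phrase "randomly split" also admits. Assignment is by
within-group shuffling and balanced dealing, with rejection-resampling
should a count bound fail.

Per protein and fold, a two-sample Welch t-test (unpooled variances,
Welch–Satterthwaite degrees of freedom) compares CCA against BBTD. A protein
is *differentially expressed* (DE) only if its two-sided p-value is below
α = 0.01 in **all** k folds. Which samples each fold tests is genuinely
ambiguous in the source description ("all data sets in the fold
validation"): we default to each fold's *training* set, because 13–17
samples per group support a t-test while 2–4 barely do, and only that
reading makes the stated stringency achievable; `test_scope = "all"` exposes
the alternative of testing the full cohort per fold. No multiple-testing
correction enters the rule — the intersection over folds is the stringency
device — but a Benjamini–Hochberg-adjusted all-sample p-value is emitted as
an audit column.

A protein is *quantifiable* only with at least `min_obs_per_group = 2`
observed values per group in every tested set ("quantifiable" is otherwise
undefined in the source description; two observations is the minimum that
admits a variance). Degenerate cases follow the limiting conventions: both
group variances zero with equal means gives p = 1, with unequal means p = 0;
a group with fewer than two observations makes the protein unquantifiable
rather than raising an error.

## Welch test from summary statistics

`welch_from_summary()` evaluates the identical formulas from (mean, SD, n)
triples, which lets published mean ± SD tables be audited without raw data.
`audit_summary_table()` applies it to the packaged transcription of the
reference study's 93-row DE protein table (`de_summary_reference()`) and
flags rows whose recomputed p fails the stated cutoff, rows whose *printed*
p fails it (one row prints p = 0.012 against a claimed P < 0.01), and
direction labels contradicting the sign of the mean difference. The printed
per-protein p-values are not all reproducible as single all-sample Welch
tests — how they were aggregated over the six folds is not stated — so the
package reports its own max-per-fold p and makes no claim of matching the
printed column.

## Unsupervised validation views

- **Hierarchical clustering** (`cluster_heatmap()`): per-protein z-scores
  clipped to ±3 for display, Euclidean distance, average linkage — the
  defaults of MeV-style expression heatmaps; both are configurable since the
  source names neither. The 2-cluster cut of the sample tree is compared
  with the group labels and the misassignment count (best cluster-to-group
  matching) is reported.
- **PCA** (`pca_scores()`): samples as observations, centred (unscaled)
  protein features — values are already rank-normalized, so unit-variance
  scaling is off by default. Missing entries are imputed at the protein's
  observed mean (a zero-information placement) rather than dropping the
  protein, since at a 5% missing rate most proteins would otherwise be lost;
  `na_action = "drop"` restores the strict behaviour. A separation index
  (between-centroid distance over mean within-group distance to centroid in
  the first three components) summarizes group separation; values above 1
  indicate separation beyond the within-group spread.
- **Volcano** (`volcano()`): log2 fold change (CCA − BBTD) against −log10 of
  the worst per-fold p, flagged at strict p < cutoff. The worst fold p is
  the pipeline's analogue of the single published p per protein, whose
  definition is unstated.
- **Box summaries** (`top_protein_boxes()`): five-number summaries per group
  with quartiles by linear interpolation (`quantile` type 7, documented and
  fixed for reproducibility), defaulting to the top five DE proteins by
  absolute fold change.

## Clinical cohort comparison

`compare_cohorts()` fixes the variable-to-test mapping that "where
appropriate" leaves open: sex by Pearson chi-squared on the 2×2 table
(without Yates correction by default — the source names the plain Pearson
test — with a flag to enable it), age by Student's t, and the right-skewed,
assay-censored markers CEA and CA19-9 by Mann-Whitney U (exact for ≤ 20
samples total without ties, tie-corrected normal approximation otherwise).
Significance is flagged at 0.05. The published sex p-value (0.085) is not
reproducible from the printed 10:7 vs 10:9 counts under any standard 2×2
test (Pearson gives X² = 0.139, p ≈ 0.71); the package reports its own
computation.

## The synthetic-data generator

`simulate_cohort()` and `simulate_matrix()` emulate the reference cohort at
the point where the analysis starts — the protein quantitation matrix — not
the spectra or identifications behind it. The model is additive on the log2
scale:

value(i, j) = baseline_i + effect_i · [group_j = CCA] + shift_j + ε_ij,
  ε_ij ~ N(0, σ_i²)

with defaults calibrated to the published cohort: 19 CCA vs 17 BBTD, 951
proteins; true effects uniform in 0.25–1.7 log2 units (the printed range of
group-mean differences), signs split evenly between directions; per-protein
SDs uniform in 0.1–0.9 (the printed SD range); baselines uniform in −2.6 to
2.4 (the printed value range — the source never states the units or dynamic
range of its ratios, so this is a declared assumption); a per-sample shift
N(0, 0.2) that exists precisely so median normalization has something to
remove; 10% of proteins truly differential (≈ the 94/951 selected fraction);
and 5% of entries missing completely at random. A left-censored missingness
option (low values preferentially masked, as abundance-dependent dropout
would produce) is available but off by default because the source does not
characterize its missingness. Clinical covariates are drawn from the printed
per-group descriptors: ages normal with the printed means/SDs, sex from the
printed male:female proportions, CEA and CA19-9 lognormal around the printed
medians and clipped to the printed (assay-saturated) ranges; the lognormal
spreads (sdlog 1.3 and 2.4) were chosen once so that the printed min–max
ranges are plausible for the group sizes.

What passing tests on these simulations do **not** show about real sera:
Gaussian log2 noise has no heavy tails or outlier samples, missingness is
(by default) independent of abundance, proteins are independent (no
correlation structure from shared pathways or shared precursors), and there
is no batch structure beyond the scalar per-sample shift. Results on
synthetic data therefore bound the procedure's behaviour under its own
assumptions, not under every failure mode of label-free data.

## Numerical choices and degenerate inputs

- Median of an even count = mean of the two middle values.
- Variances are computed in one pass and clipped at zero against
  cancellation error.
- `log2_transform()` refuses matrices already on the log2 scale (a stage
  record travels with the table) and names the first offending
  protein/sample on non-positive input.
- A sample column with no observed values is an error in every
  normalization stage.
- Fold assignment, simulation and the pipeline share one master seed with
  fixed per-stage offsets, so stages rerun standalone reproduce the
  pipeline's draws; reruns are byte-identical.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the procedure at the
published scale where it matters (951 proteins × 36 samples for null
calibration, 20 replicates; 200 replicates of 60-protein matrices for
sensitivity; 100 fold plans for bound compliance) and at reduced scale for
structural checks, a balance chosen to keep the default runs fast while
estimating each rate with usefully small Monte-Carlo error.

## Known limitations

- The headline dataset-dependent counts of the reference study (951
  identified, 94 selected, 32 up / 62 down, the two clustering exceptions)
  depend on undeposited raw data and are not reproduction targets; the
  package reproduces the *procedure* and the printed summary-statistic
  checks.
- Quantile normalization assumes most proteins are not differential;
  with very large differential fractions it compresses true effects.
- The intersection rule's false-positive behaviour depends on the overlap
  between training sets (folds share ~80% of samples), so per-fold p-values
  are strongly dependent; the null rate is bounded by, and in practice far
  below, the single-fold α.
```{r example}
cfg <- sim_config(n_proteins = 200, seed = 7)
design <- simulate_cohort(cfg)
sim <- simulate_matrix(cfg, design)
de <- sim$matrix |>
  normalize_intensity() |>
  select_de(design, build_folds(design, seed = 7))
glance(de)
```
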