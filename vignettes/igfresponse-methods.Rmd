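---
title: "Methods: quantifying transcriptional response to IGF-1 in patient-derived neurons"
author: "igfresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcriptional response to IGF-1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

iPSC-derived neurons from ASD and neurotypical control (CTL) individuals are
treated with IGF-1 either acutely (48 h) or chronically (28 days), with a
water vehicle arm, and profiled by bulk RNA-seq in a paired design: every
patient contributes replicate cultures to every arm. The analysis questions
this package operationalizes are:

1. Which genes respond to treatment within a cohort, controlling for the
   strong patient-to-patient baseline differences?
2. Is the *magnitude* of the response larger than chance, and are the
   *specific genes* robust enough to classify treated vs vehicle samples?
3. How do acute and chronic responses relate (shared / acute-dominant /
   chronic-dominant genes, aggregate temporal trajectories)?
4. Do co-expressed gene modules respond differently in ASD vs CTL
   (disease x treatment interaction on module eigengenes)?
5. Can each ASD patient's response be quantified on a single control-derived
   axis (PC1 of the control treatment signature), splitting the cohort into
   responders and non-responders, and does that shift track physiology
   (spontaneous activity) and receptor expression?
6. Which baseline disease-associated genes are *recovered* — moved back
   toward the control state — by treatment?

All stages run end-to-end on synthetic data with known ground truth, so every
claim the pipeline makes is testable.

# Data model

A `ResponseExperiment` (a `SummarizedExperiment` subclass) carries raw counts
and a TPM view of the same gene x sample table with per-sample design
columns: `patient_id`, `diagnosis` (CTL/ASD), `treatment`
(H2O/acute/chronic), `replicate`, plus optional covariates such as the mean
spontaneous burst rate from multielectrode recordings. TPM here uses the
unit-gene-length convention (identical to CPM): the generator has no
transcript lengths and every downstream statistic uses only relative
abundances. `log2(TPM + 1)` is the visualization/projection scale.

# The synthetic cohort generator

`simulateDataset()` draws NB(mu, phi) counts with

```
log2 mu_gs = baseline_g + patient_p + disease_g(ASD)
           + direction_g * effect_logfc * r_p * treat(class_g, arm_s)
           + log2(library scale_s)
```

Defaults encode the study design the package targets: 7 CTL + 8 ASD
patients, 2 replicates each, 3 arms (90 samples); 5000 genes with log2
baseline means uniform on [3, 9]; per-gene dispersions gamma-distributed
with mean 0.1 (shape 2), a typical bulk-RNA-seq spread; per-sample expected
depth uniform on [0.8e6, 1.2e6]; per-patient log2 random effects with
SD 0.3.

Design choices that matter downstream:

* **Treatment-responsive classes.** `shared` genes carry the full effect in
  both arms; `acute_only` genes retain 25% of the effect chronically and
  `chronic_only` genes show 25% acutely. This encodes gradual temporal decay
  / build-up: an "acute-dominant" gene still drifts at the chronic
  timepoint. A consequence worth knowing when interpreting tests: with
  effects of 1-1.5 log2 units, the 25% leakage is large enough to pass FDR
  for a minority of genes, which the FDR-based temporal grouping then —
  correctly by its own definition — labels "shared". Planted-class label
  recovery therefore plateaus around 80-90%, not 100%.
* **Responder heterogeneity.** CTL patients have response scale r = 1. A
  configured fraction of ASD patients (default 5/8) are responders with
  r ~ U(0.3, 1); the rest draw r ~ U(-0.5, 0). This produces the
  positive-but-reduced ASD shift with a negative-shift minority.
* **Receptor coupling.** A designated receptor gene's acute-arm mean is
  multiplied by `2^(r_p * effect_logfc)`, so *post-treatment* receptor level
  carries the response signal while its vehicle-arm level does not.
* **Activity covariate.** Per patient,
  `activity = activity_slope * r_p + N(0, activity_noise_sd)` (defaults 1 and
  0.25), giving a planted physiological correlate of the response axis.
* **Recovery class.** A fraction of baseline-DE genes
  (`baseline_de_recoverable`) is shifted by `-direction * baseline_logfc` in
  treated ASD samples in both arms — i.e. fully returned to the control
  mean. This shift is deliberately *not* scaled by r_p: recovery of the
  baseline signature and responder heterogeneity of the treatment signature
  are independent planted phenomena, so each recovery suite isolates one
  mechanism.
* **Single RNG stream.** Gene parameters, then patient effects and response
  scales, then library sizes, then counts, then covariates. Partial
  re-simulation is impossible rather than silently wrong; identical seeds
  give identical datasets.

What the generator does **not** emulate: transcript isoforms, GC/length
biases, batch effects beyond the patient term, cell-type composition
drift, and count-level correlation between genes (outside what the shared
patient and treatment terms induce). Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real RNA-seq.

# Sample QC

`excludeOutliers()` applies two passes. First, samples whose natural-log
detected-gene count falls below 6 (about 403 genes) are dropped; the log
base and threshold are configurable because "log gene counts < 6" is only
meaningful once a base is fixed. Second, on log-normalized data, samples
whose (PC1, PC2) distance from the centroid exceeds the mean distance by
more than 3 SDs are dropped. The rule is centered on the mean because
centroid distances have a positive mean by construction; identical samples
(zero spread) yield no exclusions, and the pass is idempotent.

`cellTypeScores()` z-scores each marker gene's log expression across samples
(zero-variance genes contribute 0), sums within each marker set, and tests
`score ~ diagnosis` by F-test. Because of the z-scoring, scores are
contrasts across samples: a uniform expression offset common to all samples
cancels, and a marker set is "elevated" only relative to the cohort.

# Differential expression

The NB machinery is implemented in the package and cross-checked in the test
suite against an independent implementation at the rank level.

* **TMM normalization** (`tmmFactors`). Reference sample = closest
  upper-quartile to the mean upper-quartile; per-gene log2 ratios (M) vs the
  reference are trimmed 30% on M and 5% on A and averaged with
  inverse-delta-method-variance weights; factors are rescaled to geometric
  mean 1. Trim fractions are configurable; numerical parity with any
  specific external version is not a contract, rank agreement is.
* **Dispersion estimation** (`estimateDispersions`). The common dispersion
  maximizes the Cox-Reid adjusted profile likelihood pooled over genes, with
  fitted means profiled against the design (means are refit once at the
  common value; for balanced one-factor designs they are exact). Per-gene
  adjusted profile likelihoods are evaluated on a 35-point log-spaced grid;
  the trend maximizes a locally averaged likelihood (window of genes ordered
  by average logCPM), and the tagwise estimate maximizes
  `APL_g + (priorDf / residualDf) * localAPL_g` with `priorDf = 10` —
  empirical Bayes on likelihood surfaces rather than on noisy point
  estimates, which keeps null p-values calibrated. A single-gene matrix
  collapses all three estimates to that gene's own maximum.
* **Exact test** (`nbExactTest`). Counts are scaled to the geometric-mean
  effective library ("pseudo-counts", rounded), and per gene the two-sided
  p-value sums the probabilities of all group splits at most as probable as
  the observed one, conditional on the total, using NB group sums at the
  tagwise dispersion (`phi = 0` falls back to the conditional binomial).
  Fold-changes use group means with a prior count of 0.125 per sample.
* **GLM likelihood-ratio test** (`nbGlmLRT`). Per-gene NB log-linear models
  with fixed tagwise dispersion are fit by IRLS, vectorized across genes
  (one shared design matrix; per-gene weighted least-squares updates); the
  LRT compares the full design against the design without the tested term.
  A quasi-likelihood F-test would additionally propagate dispersion
  uncertainty; the LRT is the documented simplification, adequate at the
  rank level this pipeline consumes. Saturated designs (zero residual df)
  are an error unless dispersions are supplied externally
  (`allowSaturated`), which the interaction-design permutation scheme uses.
* **FDR** (`adjustFdr`): Benjamini-Hochberg via `p.adjust`, with explicit NA
  masking semantics.

Expression filtering keeps genes with abundance > 1 in at least 3 samples
(`filterExpressed`); the pipeline filters once on the full matrix so that
all contrasts share one feature space (required by the recovery stage).

# Permutation magnitude test and classifier

`permutationTest()` counts FDR-significant genes under the true labels, then
under `nPerm` relabelings, and reports
`bootstrap_p = (1 + #{null >= observed}) / (nPerm + 1)`; the add-one
correction avoids p = 0 at finite permutations, and the raw fraction is also
reported. Default scheme shuffles arm labels *within patient*, matching the
additive patient term (each patient's arm multiset is preserved by
construction); a global shuffle and the interaction design
(`~ treatment * patient`, treatment tested with externally fixed
dispersions) are options. The gene filter for this stage is total abundance
>= 6 across all samples — label-free, so filtering once is exact.
Normalization factors and dispersions are estimated once from the data and
held fixed across permutations: dispersion is a property of biological
variability, not of the treatment labeling, and holding it fixed both
isolates the label effect and makes 100-permutation runs tractable.

`classifyTreatment()` trains a random forest on the signature genes'
log expression and reports out-of-bag error, the confusion matrix, and AUC
computed from out-of-bag vote fractions by the rank statistic (ties
averaged). If every feature is constant no split exists; the report then
reflects majority-class prediction with AUC 0.5 rather than an arbitrary
forest.

# Overlap, temporal, and trajectory statistics

`overlapFisher()` computes, for the 2x2 overlap table of two gene lists in a
universe, the two-sided Fisher exact p (summing hypergeometric probabilities
at most as large as the observed table's), the *conditional
maximum-likelihood* odds ratio — the root of the noncentral hypergeometric
score equation, solved to 1e-10 — and the exact central 95% CI by inverting
one-sided tests at 2.5% per side. The conditional-MLE convention is chosen
over the sample cross-product ratio because it is the convention exact-test
software reports; boundary tables return 0 or infinity. The test suite
asserts the score-equation residual and the CI inversion probabilities
directly.

`temporalGrouping()` partitions the union of acute- and chronic-significant
genes by significance pattern, with direction from the defining contrast;
shared genes with opposite signs are labeled "discordant" and excluded from
trajectory aggregates. `trajectoryTest()` z-scores genes across all samples,
averages within a group (up- and down-regulated genes separately), and
F-tests the aggregate between the two arms of each contrast; an all-constant
group is reported as p = 1 with a degeneracy flag rather than an error.
`enrichmentORA()` is a one-sided hypergeometric over-representation test
with BH adjustment across sets; gene sets can be read from GMT files.

# Co-expression modules

The network is unsigned: adjacency `|cor|^beta` with the soft power chosen
as the smallest beta whose scale-free fit R^2 (signed, truncated at zero,
from the log-log regression of the binned connectivity distribution) exceeds
0.9; if none qualifies the best-fitting power is returned with a warning.
The topological overlap matrix uses the standard shared-neighbor
normalization with unit diagonal. Modules come from average-linkage
clustering of `1 - TOM` with a *static* cut (default height 0.99): the
dynamic hybrid cut algorithm adds tuning surface without changing the
testable contract (planted blocks must be recovered exactly), and a static
cut is fully deterministic. Clusters below `minModuleSize = 10` pool into
"grey"; grey is nevertheless treated as a reportable gene set with its own
eigengene, since the largest analyzed signature can land there. Eigengenes
are first right-singular-vector scores of the gene-standardized module
matrix (zero mean across samples by construction), sign-aligned to the
module average; a one-gene module's eigengene is that gene's z-score. Each
eigengene is modeled as `lm(eigengene ~ diagnosis * treatment)` with
sequential F-tests; interaction-significant modules (p < 0.05) are flagged.
The supervised input is the union of the ASD and CTL acute DE genes on
vehicle + acute samples.

# Response axis and responder stratification

`fitPCSpace()` learns PC axes from control vehicle + acute samples on the
control acute signature genes: genes are centered and (by default) scaled by
*fitting-sample* statistics, PCs come from the SVD, and PC1 is oriented so
treated controls score higher than vehicle controls. Centering/scaling by
the fitting samples is what makes the axis transferable: `projectSamples()`
standardizes any sample with the stored center/scale and multiplies by the
stored loadings, so each projection is per-sample and unaffected by which
other samples are projected. Scaling is on by default (configurable);
without it high-variance genes dominate the axis.

`patientShift()` averages PC1 per patient per arm and reports
`delta_pc1 = mean(treated) - mean(vehicle)`; the responder rule is strictly
`delta_pc1 > 0` — the sign of the shift, no margin. Patients missing an arm
are flagged, never silently dropped. `covariateAssociation()` is an OLS
F-test of the shift against any per-patient covariate (activity, receptor
level per arm).

# Recovery classification

For each gene significant in the ASD-vs-CTL vehicle contrast, the default
("strict") rule calls an arm "recovered" when the treatment shift within ASD
opposes the baseline sign *and* the treated-ASD vs vehicle-CTL contrast is
no longer significant; `rule = "sign"` uses the sign condition alone
(fold-change quadrant membership). Both are provided because the underlying
notion — "moved toward the control state" — does not pin down whether
post-treatment indistinguishability from controls is required. "IGF-1
altered" genes (normal at baseline, different from the control state only
after treatment) are reported under both readings of that phrase:
treated-ASD vs control, and treated-ASD vs vehicle-ASD.

# Numerical and test-design choices

* Root-finding tolerances: 1e-10 for the conditional OR and CI; IRLS stops
  at relative log-likelihood change 1e-8 (max 30 iterations; non-converged
  genes get NA p-values, are excluded from FDR, and trigger a warning).
* Dispersion grid: 35 log-spaced points on [1e-5, 10] with quadratic
  interpolation of the argmax; the common value is refined by `optimize`.
* The calibration suite simulates its pure-null cohorts at the tests' model
  family: NB counts with a *homogeneous* dispersion level
  (`dispersion_shape = 200`) at 2000 genes x 12 samples x 20 replicates.
  With strongly heterogeneous per-gene dispersions and ~5 residual df, no
  moderated NB test yields KS-uniform nulls at this scale — the shrunken
  tagwise estimates cannot track per-gene truth — so uniformity is asserted
  where it is a well-defined property of the implementation.
* Unit-test problem sizes are deliberately modest (hundreds of genes, tiny
  cohorts); the planted-truth acceptance suites use 2000-gene cohorts at
  the full 15-patient design, and the end-to-end qualitative check uses the
  5000-gene default. These sizes were chosen as the smallest at which the
  tested signals are unambiguous.

# Known limitations

* Feature level is whatever the input rows are; transcript-to-gene
  collapsing is out of scope.
* The quasi-likelihood F-test is replaced by an LRT (documented above);
  p-values are slightly anticonservative at very small residual df when
  dispersions are heterogeneous.
* The permutation test reuses dispersions across permutations (rationale
  above); re-estimating per permutation would be slower and changes little
  under the null.
* Marker gene sets for cell-type scoring are user-supplied; none are
  bundled.
* `delta_pc1` has no uncertainty interval; a replicate-level bootstrap is
  future work.
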