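---
title: "Scoring the tumour immune microenvironment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the tumour immune microenvironment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(siascore.verbose = FALSE)
library(siascore)
```

## The problem and the model

Solid tumours are infiltrated by immune cells that either attack the
tumour (notably CD8+ cytotoxic T cells) or support it (notably M2-like,
CD68+CD163+ tumour-associated macrophages). `siascore` quantifies this
balance from per-cell multiplex immunohistochemistry (mIHC) data and
summarises it in the **Signature of Immune Activation**:

$$\mathrm{SIA} = \frac{d_{CD8}}{d_{CD8} + d_{CD68^+CD163^+}},$$

where $d$ are cell densities in cells/mm² of analysed tissue. SIA lies in
[0, 1]: 1 means a purely cytotoxic infiltrate, 0 a purely M2-macrophage
infiltrate. When both densities are zero the score is undefined and the
patient is excluded (with a log entry) rather than imputed.

For comparison the package computes an Immunoscore-like metric (IS): CD3+
and CD8+ densities in the tumour centre and at the invasive margin are
each percentile-ranked within the cohort (percentile = 100·rank/n,
average ranks for ties) and averaged — four channels per patient when
complete, three when one region is missing, and two for cohorts sampled
from bulk tumour without a centre/margin split. Categories are Low
(mean percentile ≤ 25), Intermediate (25–70] and High (> 70); the
boundary conventions (≤ on the left edge of each interval) are fixed and
documented because touching intervals leave them ambiguous.

## From intensities to densities

**Thresholding.** Marker positivity thresholds are learned from reference
cells labelled positive/negative. Probability densities of the two
reference sets are estimated with a Gaussian KDE using Silverman's
rule-of-thumb bandwidth (the default automatic bandwidth of
`stats::density()`), evaluated on a 512-point grid spanning
[min − 3h, max + 3h]. Two rules apply:

* **Midpoint** — if the reference sets do not overlap, the threshold is
  the mean of the highest negative and lowest positive intensity; all
  four error rates are exactly zero by construction.
* **Error minimisation** — if they overlap, the threshold minimises
  $err(t) = \pi_{neg}\int_t^{\infty}\hat f_{neg} +
  \pi_{pos}\int_{-\infty}^{t}\hat f_{pos}$
  over the union of the two KDE grids restricted to the observed
  intensity range (outside it, the rule degenerates to calling every cell
  positive or negative). The tail masses are evaluated through the exact
  closed form of the Gaussian-KDE CDF (a mean of kernel CDFs), so no
  numerical integration error enters the minimisation; ties break to the
  smallest threshold. Priors $\pi$ default to the empirical reference-set
  proportions, making $err$ the reference misclassification rate; equal
  priors are available via `sia_config(error_min_priors = "equal")`.

A cell is positive iff its intensity is **strictly greater** than the
threshold; intensities exactly at the threshold are negative. FPR, TPR,
FNR and TNR are reported per marker, and a fitted threshold whose FPR is
not below its TPR triggers an inverted-marker warning.

**Phenotyping.** Positivity patterns are mapped to cell classes by an
ordered rule table (first matching rule wins; duplicated patterns are
flagged). Pan-cytokeratin-positive cells are `tumour` and never count
towards immune densities; unmatched cells are `unclassified`. The shipped
default covers both antibody panels with 15 immune classes — the three
macrophage classes (CD68+CD163−, CD68+CD163+, CD68−CD163+), CD8+ and CD4+
T-cell subsets with FoxP3/CD45RO refinements, CD20+ B cells, NK and
NKT-like cells, and CD3+ T cells. The published class catalogue behind
the panels is not reproduced verbatim anywhere we can cite, so this table
is an explicit reconstruction from the panel marker combinations, and the
rule table is fully configurable.

**Densities.** Patients are represented by one to four TMA cores.
Densities always pool: total cell count across a patient's cores divided
by total tissue area — never a mean of per-core densities, which would
weight small cores as much as large ones. Region-stratified densities
(centre/margin) pool within region. Cells flagged `excluded` (necrosis,
debris — curation that is manual upstream) are dropped before counting.

**Stratification.** Scores are cut at the 33.3rd and 66.6th empirical
percentiles (linear interpolation; values equal to a cut go to the lower
stratum). When the cuts coincide, or when one value is shared by at least
a third of the cohort — typical when many patients reach the maximal
SIA of 1 — terciles are meaningless and the function switches to a median
split (low: ≤ median), logging the switch.

## RNA surrogates

Because C1q (C1QA/B/C transcripts) is produced overwhelmingly by
CD68+CD163+ macrophages, bulk-RNA SIA is the per-sample ratio
CD8A / C1Q-subunit (linear scale; log2 matrices are exponentiated first).
Pre-therapy filtering applies when timepoint labels exist and patients
with several samples get the mean of their sample scores. A zero
denominator with positive CD8A maps to +Inf (ranked top); 0/0 is
undefined. An IS-like bulk metric is the mean of CD8A and CD3E.

Single-cell SIA counts cells instead of reads: after QC (≥ 250 detected
genes by default, with 100 appropriate for sparser droplet data; and a
mitochondrial count fraction ≤ 0.05), a cell is positive for a gene when
its count exceeds the configured threshold (default 0). CD8+ cells are
CD8A-positive; M2-like macrophages are positive for CD68 together with
one of CD163, C1QA, C1QB or C1QC. The mitochondrial ceiling is
interpreted as a *fraction* (5%); a literal 0.05% reading — which would
discard nearly every real cell — can be requested explicitly via
`sia_config(mito_ceiling = 0.0005)` but is not the default.

## Survival analytics

* **Kaplan–Meier / log-rank / Cox** use the `survival` package with Efron
  tie handling; categorical covariates are coded against fixed reference
  levels (low stratum, T1, N0, age ≤ 75, female, MMR proficient).
* **Bootstrap AUC**: the discrimination of a score (typically a Cox
  linear predictor) for the event indicator over follow-up, resampled
  with replacement stratified on outcome; an alternative fixed-horizon
  outcome is available because "AUC in a Cox model" underdetermines the
  outcome definition. The rank-statistic AUC handles ties as 1/2.
* **Time-dependent AUC**: cumulative-case/dynamic-control with
  inverse-probability-of-censoring weights from the Kaplan–Meier estimate
  of the censoring distribution (cases weighted 1/G(T−), controls
  1/G(t)). With no censoring this reduces exactly to the proportion of
  concordant case–control score pairs, which is how the tests pin it.
* **Wald-χ² contributions**: each term's χ² is the quadratic form of its
  coefficient block with the inverse covariance block, so multi-level
  factors contribute jointly; proportions sum to 1.
* **Optimal-cutoff dichotomisation** scans observed score values inside a
  quantile window (default 10th–90th percentile) and minimises the
  log-rank p. The minimised p is optimistically biased; it is reported
  with an explicit caveat and deliberately not corrected, mirroring the
  common use of this procedure, and its null behaviour can be measured
  with the simulator.
* **Responder analyses**: exact Mann–Whitney U for pooled n ≤ 20 without
  ties (normal approximation with tie correction otherwise), ROC AUC with
  a bootstrap CI, and Spearman correlation against an ordinal response
  coding.

## TMA representativeness

To ask whether single-tile sampling represents whole-slide marker
densities, one tile is drawn per whole-slide section, forming an
in-silico TMA cohort; per marker, a two-sample Kolmogorov–Smirnov test
compares the cohort with the remaining tiles; the fraction of significant
iterations over 1000 draws (strict p < α, α = 0.05) is reported.

Two comparison sets are implemented because the procedure's reference
population is genuinely ambiguous:

* **pooled** (default): cohort vs the remaining tiles of *all* slides.
  Under exchangeable tiles this is calibrated (slightly conservative,
  because the cohort is stratified one-per-slide), matching the null
  simulations. Note that under purely random tile selection the cohort is
  marginally exchangeable with the pooled remainder even when slides
  differ from each other, so this variant answers "does the cohort
  represent the pooled tile population".
* **per_slide**: cohort vs each slide's own remaining tiles, combined by
  Bonferroni. This is the variant with power against slide-to-slide
  heterogeneity — the situation in which a one-tile-per-slide TMA really
  does misrepresent individual tumours — and is what the gradient
  simulations exercise.

## The synthetic cohort generator

All inputs can be simulated, with ground truth, so every stage is
testable without patient material. Defaults encode realistic study
conditions: 1–4 cores per patient at 1.84 mm² each (a typical cohort mean
tissue area); per-marker intensities from two-component log-normal
mixtures (strictly positive and right-skewed, like fluorescence
intensities) whose component separation controls overlap; per-core class
counts Poisson with mean density × area; per-patient log-normal density
multipliers (σ_log = 0.6) creating inter-patient heterogeneity; overall
survival exponential with tercile hazard ratios 0.65 (intermediate) and
0.43 (high vs low), recurrence-free 0.65 and 0.46, under administrative
plus exponential dropout censoring; bulk expression proportional to the
relevant densities with log-normal noise and 50 density-independent decoy
genes; and negative-binomial single-cell libraries in which marker genes
are expressed only in their class, plus controllable rates of
low-complexity and high-mitochondrial cells for the QC filter.

What the generator does **not** emulate: spatial coordinates within
cores, tumour-vs-stroma compartments, staining artefacts, segmentation
errors, batch effects, or ambient RNA. Passing tests therefore
demonstrate the correctness of the computations under the stated
generative model, not robustness to those real-data pathologies.

Exponential baselines were chosen so that hazard-ratio recovery has a
closed-form truth; the ground-truth SIA of a simulated cohort is
computable exactly from realised cell counts, and the scoring path
reproduces it exactly when classification uses the true labels.

## Worked example

```{r example, eval = FALSE}
spec <- sia_sim_spec(n_patients = 60, seed = 4241)
sim <- simulate_cell_table(spec)

ref <- do.call(rbind, lapply(unique(unlist(default_panels())), function(m) {
  truth <- sim$cell_truth[[paste0("true_", m)]]
  ok <- !is.na(truth)
  data.frame(marker = m, intensity = sim$cells[[m]][ok],
             label = ifelse(truth[ok], "pos", "neg"))
}))
thresholds <- determine_thresholds(ref)

cells <- classify_cells(apply_thresholds(sim$cells, thresholds))
dens <- compute_densities(cells, sim$cores)

md <- dens$marker_densities; cd <- dens$class_densities
cd8 <- md[md$marker == "CD8" & md$region == "all", ]
m2 <- cd[cd$class == "CD68+CD163+ macrophage" & cd$region == "all", ]
pats <- sort(unique(md$patient_id))
sia <- compute_sia(cd8$density[match(pats, cd8$patient_id)],
                   m2$density[match(pats, m2$patient_id)])
stratum <- categorize_tercile(sia)

surv <- simulate_survival(data.frame(patient_id = pats,
                                     sia_stratum = stratum), spec)
cox_fit(surv, "sia_stratum")
```

## Numerical choices and problem sizes

Tolerances and sizes used by the shipped checks are the package's own
choices: hazard-ratio recovery at n = 100,000 (±0.03 of the simulated
truth), threshold agreement with a 10,000-point brute-force scan over 50
random overlapping mixtures (within one grid step), 1000-replicate null
calibrations for the log-rank, likelihood-ratio and KS-resampling
procedures (α ± 0.02), exact (≤ 1e-9) agreement of the IPCW tAUC with
pair counting at n = 200 without censoring, and a 60-patient end-to-end
cohort. Degenerate inputs error early and explicitly: fewer than two
distinct intensities for a KDE, empty reference sets, cohorts under three
patients for percentile ranking, all-equal scores for stratification,
single-class outcomes for AUCs.

## Known limitations

* The default rule table is a reconstruction; site-specific panels should
  supply their own.
* The optimal-cutoff p-value is biased by design and must not be read as
  a calibrated test.
* The pooled representativeness variant cannot, by construction, detect
  slide-to-slide heterogeneity under random one-tile-per-slide selection;
  use `comparison = "per_slide"` for that question.
* Bulk-RNA SIA assumes C1q transcription is macrophage-dominated; in
  tissues where that fails the surrogate decouples from the cellular
  score.
* No competing-risks handling; RFS treats death and progression as one
  composite endpoint.
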