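# siascore

Quantifying the balance between anti-tumoural and tumour-supportive
immune infiltration from multiplex immunohistochemistry (mIHC) and RNA
data.

Tumour-infiltrating CD8+ cytotoxic T cells predict longer survival in
several solid cancers; CD68+CD163+ (M2-like) tumour-associated
macrophages predict shorter survival. `siascore` implements an
end-to-end pipeline for pathology and biomarker groups that turns
per-cell mIHC marker intensities into the **Signature of Immune
Activation**

```
SIA = d(CD8+) / ( d(CD8+) + d(CD68+CD163+) )        d = cells / mm²
```

together with an Immunoscore-like mean-percentile metric (IS), their
survival associations, RNA-level surrogates (bulk: the CD8A/C1QA–C
ratio; single-cell: marker-positive cell counting), and a resampling
test of whether tissue-microarray sampling represents whole slides.

## What the package does

* **Thresholding** — per-marker positivity thresholds from labelled
  reference cells: midpoint rule for non-overlapping references, KDE
  error-minimisation (Silverman bandwidth, exact Gaussian-mixture CDFs)
  for overlapping ones, with FPR/TPR/FNR/TNR reporting.
* **Phenotyping** — configurable ordered marker-combination rules
  (default: 15 immune classes over a lymphocyte and an NK/macrophage
  panel); area-pooled densities per patient and region.
* **Scoring** — SIA, cohort-percentile IS (centre+margin or bulk mode),
  tercile stratification with a median-split fallback for ceiling-heavy
  cohorts, bulk and single-cell RNA surrogates with QC filtering.
* **Survival statistics** — Kaplan–Meier/log-rank, Cox (Efron ties),
  likelihood-ratio model comparison, bootstrap AUC, IPCW time-dependent
  AUC, Wald-χ² contribution decomposition, optimal-cutoff
  dichotomisation, responder analyses (exact Mann–Whitney, ROC, Spearman).
* **Representativeness** — the in-silico TMA procedure: one random tile
  per whole-slide section vs the remaining tiles, two-sample
  Kolmogorov–Smirnov, 1000 iterations.
* **Synthetic data** — generators for every input (cell tables with
  ground-truth positivity, cores, survival under stated hazard ratios,
  bulk/single-cell expression, tile grids), so the whole pipeline is
  testable without patient material.

A thin command-line wrapper ships in `inst/scripts/siascore`
(subcommands `simulate`, `threshold`, `phenotype`, `score`, `survival`,
`representativeness`, `rna-score`, `sc-score`).

## A worked example

```r
library(siascore)

spec <- sia_sim_spec(n_patients = 60, seed = 4241)
sim  <- simulate_cell_table(spec)

ref <- do.call(rbind, lapply(unique(unlist(default_panels())), function(m) {
  truth <- sim$cell_truth[[paste0("true_", m)]]
  ok <- !is.na(truth)
  data.frame(marker = m, intensity = sim$cells[[m]][ok],
             label = ifelse(truth[ok], "pos", "neg"))
}))
thresholds <- determine_thresholds(ref)
head(thresholds[, c("marker", "threshold", "rule", "fpr", "fnr")], 3)
#>   marker threshold      rule          fpr          fnr
#> 1  CD163  3.770255 error_min 5.846130e-05 0.0003134375
#> 2   CD20  4.131397 error_min 1.736539e-05 0.0012673326
#> 3    CD3  3.444387 error_min 2.220544e-04 0.0001219215

cells <- classify_cells(apply_thresholds(sim$cells, thresholds))
dens  <- compute_densities(cells, sim$cores)

md  <- dens$marker_densities; cd <- dens$class_densities
cd8 <- md[md$marker == "CD8" & md$region == "all", ]
m2  <- cd[cd$class == "CD68+CD163+ macrophage" & cd$region == "all", ]
pats <- sort(unique(md$patient_id))
sia  <- compute_sia(cd8$density[match(pats, cd8$patient_id)],
                    m2$density[match(pats, m2$patient_id)])
summary(sia)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.4267  0.6756  0.7602  0.7485  0.8385  0.9512

stratum <- categorize_tercile(sia)   # cuts at the 33.3/66.6 percentiles
surv <- simulate_survival(data.frame(patient_id = pats,
                                     sia_stratum = stratum), spec)
cox_fit(surv, "sia_stratum")
#> Cox proportional hazards fit (60 subjects, 37 events)
#>         term                   level    hr ci_lo ci_hi wald_p
#>  sia_stratum sia_stratumintermediate 0.715  0.33  1.55   0.40
#>  sia_stratum         sia_stratumhigh 0.557  0.25  1.24   0.15
```

The fitted hazard ratios point the planted way — intermediate and high
SIA terciles have a lower death hazard than the low tercile (simulated
truth 0.65 and 0.43) — though a 60-patient cohort is far too small for
the intervals to exclude 1; the hazard-ratio recovery check in
`scripts/acceptance.R` refits at n = 100,000 where the estimates land
within ±0.03 of the truth. Thresholds separate the simulated intensity
mixtures almost perfectly (error rates near zero), and the SIA
distribution is skewed towards 1, which is why the tercile function
carries a median-split fallback for ceiling-heavy cohorts.

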