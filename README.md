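# serialdex

Serial tumor gene-expression analysis for neoadjuvant chemotherapy (NAC)
studies.

Patients on NAC can be biopsied repeatedly: before treatment (**T1**), 24–96
hours after the first dose (**T2**), and at surgery (**TS**, residual tumor).
`serialdex` is an R package for the statistical workflow such serial designs
need — for translational researchers asking which genes a first chemotherapy
cycle perturbs, whether early expression *changes* separate responders from
nonresponders, and whether residual-tumor expression predicts recurrence.

The package covers, as composable tibble-in/tibble-out functions:

* **Normalization** — probe-to-gene collapsing by replicate averaging, and
  print-batch correction by fitting the per-gene linear model
  *x<sub>gs</sub> = β<sub>batch(s)</sub> + ε* and keeping the residuals
  (equivalently, per-batch mean centering).
* **Paired permutation differential expression** — per gene, the paired
  t-statistic *t = d̄ / (s<sub>d</sub>/√n)* is referenced to the sign-flip
  null (all 2ⁿ flips when feasible, otherwise Monte-Carlo with the identity
  always counted, so *p ≥ 1/total*), with Benjamini–Hochberg FDR control at
  adjusted *p* < 0.05.
* **Response contrasts** — Welch-t label-permutation tests comparing RCB 0/I
  (responders) vs RCB II/III (nonresponders) on static values (T1, T2) or
  early changes (T2 − T1), thresholded at raw *p* < 0.005 without
  multiplicity correction, matching the small group sizes such cohorts
  allow.
* **Molecular subtyping** — generic nearest-centroid classification against
  a user-supplied panel (e.g. PAM50-style centroids), with paired
  concordance rates and full transition tables.
* **Survival screens** — per-gene Cox proportional-hazards models of
  recurrence-free survival (RFS) on T1, TS or TS − T1 covariates
  (likelihood-ratio tests, optional hormone-receptor adjustment), tertile
  dichotomization, Kaplan–Meier curves, log-rank tests, and an exact paired
  Wilcoxon signed-rank test.
* **Enrichment** — one-sided Fisher exact (hypergeometric tail)
  overrepresentation of significant genes against GMT gene sets, with the
  tested genes as universe.
* **Synthetic cohorts** — a fully documented generator
  (`sim_config()` / `simulate_cohort()`) with subtype-centroid structure,
  print-batch offsets, incomplete pairing, a planted on-treatment
  downregulation of proliferation/immune genes, response-linked expression
  deltas, and TS-expression-linked recurrence hazards, so every stage is
  testable without clinical data.

`run_all()` chains the whole workflow and writes per-stage TSVs plus a JSON
summary of every count (significant features per contrast, up/down splits,
concordance rates, transition tables, set overlaps).

## Worked example

```r
library(serialdex)

sim  <- simulate_cohort(sim_config(seed = 1))   # 48 patients, 2000 genes
expr <- residualize_batch(sim$expr, sim$meta)   # remove print-batch offsets

# paired permutation test, pretreatment vs early on-treatment
de <- run_contrast(expr, sim$meta, "t1_vs_t2", n_perm = 10000, seed = 1)
glance(de)
#>   contrast n_features n_tested n_significant  n_up n_down threshold_rule
#> 1 t1_vs_t2       2000     2000           206     2    204 BH-adjusted p < 0.05

truth_eval(de, c(sim$truth$prolif_genes, sim$truth$immune_genes))
#>   n_planted n_called n_true_positive sensitivity    fdr
#> 1       200      206             200           1 0.0291
```

Of the 2000 genes, 206 change significantly after the first dose — almost
all downregulated, recovering all 200 planted proliferation/immune genes at
an observed false-discovery proportion of 2.9%.

```r
calls <- assign_subtypes(expr, sim$centroids)
concordance(calls[grepl("_T1$", calls$sample_id), ],
            calls[grepl("_T2$", calls$sample_id), ], sim$meta)
#> Subtype concordance: 36 of 36 pairs identical (100%), 0 changed

# residual-tumor expression vs recurrence-free survival
sr <- screen_rfs(expr, sim$meta, mode = "ts")
glance(sr)
#>   mode n_features n_significant n_reduced_rfs n_increased_rfs p_threshold
#> 1 ts         2000            61            56               5       0.005
```

The TS screen (33 residual-disease patients, 14 recurrences) flags 61 genes
at raw likelihood-ratio *p* < 0.005, 56 of them with high expression linked
to reduced RFS — dominated by the 50 planted hazard genes.

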