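---
title: "Methods: serial tumor expression analysis with serialdex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial tumor expression analysis with serialdex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdex)
```

## The design

Neoadjuvant chemotherapy (NAC) cohorts with serial biopsies yield a
three-time-point expression matrix per patient: pretreatment (T1), 24–96 h
after the first dose (T2), and the residual tumor at surgery (TS). Pairing
is incomplete — not every patient has every array — and the arrays come off
several print batches with systematic additive offsets. Three scientific
questions structure the analysis:

1. *What does one chemotherapy cycle do to the tumor transcriptome?*
   Paired contrasts T1 vs T2 and T1 vs TS.
2. *Do early expression changes track response?* Two-group contrasts of
   T1, T2 and T2 − T1 between responders (residual cancer burden, RCB 0/I)
   and nonresponders (RCB II/III).
3. *Does residual-tumor expression predict recurrence?* Per-gene Cox
   models of recurrence-free survival (RFS) on T1, TS and TS − T1.

TS only exists for patients with residual disease, so every TS-based
analysis is conditional on non-pCR; outcome screens restrict further to
patients with a determinate RCB class (RCB I/II/III). This restriction is
structural, not a filtering choice: pCR leaves nothing to biopsy.

## Statistical machinery and its assumptions

**Batch correction.** Per gene, expression is regressed on print batch as a
categorical factor and replaced by the residuals. Because the design matrix
is a one-way layout, the least-squares fit has the closed form "subtract
the batch mean", which is what `residualize_batch()` computes — exact, fast
and idempotent. Missing values are excluded from the batch means; a gene
observed in a single batch is simply mean-centered. The assumption is an
additive, gene-specific batch offset; multiplicative or intensity-dependent
artifacts are out of scope (they belong to within-batch array
normalization, upstream of this package).

**Paired permutation test.** For gene differences $d_i = b_i - a_i$ over
$n$ complete pairs, the statistic is $t = \bar d / (s_d/\sqrt n)$ with the
$(n-1)$-denominator standard deviation. The null flips each $d_i$'s sign
independently — exchangeability of $\pm d_i$ under the null is the only
assumption; normality is not needed. All $2^n$ assignments are enumerated
when $2^n \le$ `n_perm` (the `exhaustive` flag records this); otherwise
`n_perm` random assignments plus the identity are used, so the two-sided
$p = \#\{|t^\*| \ge |t|\}/\text{total}$ is never zero and
$p \cdot \text{total}$ is always an integer. Ties at exactly $|t|$ (the
global sign flip always produces one) are counted into the tail under a
$10^{-12}$ relative tolerance, which keeps exhaustive p-values exactly
rational. Degenerate input ($d \equiv 0$) returns $t = 0$, $p = 1$ by
contract; zero-variance nonzero differences give $t = \pm\infty$ and the
permutation tail still behaves correctly. Pairs with a missing member are
dropped *per gene* and the per-gene $n$ is recorded; genes with fewer than
3 complete pairs are reported as untested rather than failing the contrast.

**Two-group permutation test.** The Welch (unequal-variance) t-statistic,
oriented as group 2 minus group 1, referenced to the label-reassignment
null preserving group sizes (exhaustive when $\binom{n}{n_1} \le$
`n_perm`). Welch rather than pooled-variance t is the robust default when
the statistic's variance assumption cannot be checked at $n_1 = 7$-scale
group sizes; since the reference distribution is the permutation null, the
choice affects power, not validity.

**Multiplicity.** Time-point contrasts are Benjamini–Hochberg adjusted
(step-up, with the number of tests $m$ equal to the non-missing p-values)
and thresholded at adjusted $p < 0.05$. Outcome contrasts and survival
screens deliberately use raw $p < 0.005$ with *no* correction — the
convention for small-cohort exploratory outcome screens; the package keeps
the two rules distinct and echoes them into every result's metadata. One
interaction worth knowing: with `n_perm = 10000`, the smallest attainable
raw p is $1/10001 \approx 10^{-4}$, so on a 2000-gene matrix BH can only
reject when several genes sit at the permutation floor. That makes the
pipeline conservative under the global null (null cohorts almost never
reject anything) while leaving power for planted effects essentially
untouched; raising `n_perm` sharpens the floor at linear cost.

**Subtyping.** `assign_subtype()` is a generic nearest-centroid classifier:
Spearman correlation (default; Pearson selectable) between a sample's
profile and each centroid over shared non-missing genes, argmax label,
ties broken by panel column order and flagged. At least `min_genes` (30)
shared genes are required. The full PAM50 pipeline — gene centering to a
reference population, risk-of-relapse scores — is intentionally *not*
reproduced: centroid values and calibration data are external inputs, and
the package makes no claim about them. Concordance between paired calls is
reported as a whole percentage with half-away-from-zero rounding; that
convention is forced by the arithmetic of small pair counts (24/39 must
print as 62, not 61).

**Survival.** `cox_fit()` delegates the partial-likelihood maximization to
`survival::coxph` with Breslow tie handling (Efron selectable) and reports
the likelihood-ratio test against the model without the gene — adjustment
covariates (e.g. hormone-receptor status) stay in both models, so the LR
statistic isolates the gene's contribution. The LR test, not Wald, is the
reported p throughout, applied uniformly to gene screens and to scalar
markers. Degenerate cases follow explicit contracts: constant covariate or
zero events give $\beta = 0$, $p = 1$, flagged; $|\hat\beta| > 15$ or
non-convergence in 100 iterations yields a flagged result with missing
$\beta$. Tertile dichotomization for Kaplan–Meier illustration cuts at the
type-7 (linear-interpolation) quantile; values strictly beyond the cut form
the "high" (or "low") group, so boundary ties all fall to the "rest" side —
deterministic, and documented because group sizes at small $n$ depend on
it. The paired Wilcoxon signed-rank test drops zero differences, midranks
ties, and enumerates the exact sign-flip null up to 20 nonzero differences
(beyond that, a tie-corrected normal approximation with continuity
correction).

**Enrichment.** One-sided Fisher exact overrepresentation: the p-value is
the hypergeometric upper tail of the observed overlap. The universe is the
set of genes actually tested in the upstream contrast — not the genome —
matching microarray practice and making the test self-contained. Per-set
p-values are reported raw (no multiplicity correction), with the 0.05
convention for calling a set overrepresented.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. It
generates, per `sim_config()`:

* patient subtypes from `subtype_proportions`; T1 expression
  $x = c \cdot \text{centroid} + \text{batch} + N(0, \sigma^2)$, with
  centroid signal confined to the first `n_panel_genes` genes (as in a
  50-gene classifier panel) and additive $N(0, \text{batch\_sd}^2)$
  per-(batch, gene) offsets over `n_batches = 6` print batches;
* T2 = T1 + shift with mean $-$`t2_downshift` for the planted
  proliferation and immune gene blocks; response genes receive group
  offsets weighted by the complementary group's frequency, so responders
  and nonresponders differ by exactly `response_delta_gap` while the
  cohort-mean shift is zero — the planted response signal is a contrast,
  not a marginal drift;
* TS (residual-disease patients only) = T1 + drift plus a patient-level
  frailty $u_i \sim N(0, \text{hazard\_frailty\_sd}^2)$ on the hazard gene
  block; RFS is exponential with
  $\log h = \log(\text{baseline\_hazard}) + \beta \cdot
  \overline{x}_{\text{hazard,TS}}$, censored by an independent uniform
  time on (0, `censor_time_max`]; pCR patients are censored at the
  horizon;
* incomplete pairing by dropping `frac_t2_missing` of T2 arrays and
  `frac_ts_missing` of eligible TS arrays; optionally `probes_per_gene`
  replicate probes with $N(0, \text{probe\_noise\_sd}^2)$ measurement
  noise to exercise probe collapsing.

All randomness flows from one seed through per-stage substreams, so a fixed
seed gives a bit-identical cohort regardless of which stage is consumed
first.

**Defaults and why.** 48 patients with 25% of T2 arrays dropped gives the
36 complete T1–T2 pairs typical of such cohorts; the default RCB class
distribution (17/3/44/28/8% for 0/I/II/III/undetermined) mirrors a
matched-pair neoadjuvant cohort, putting roughly a fifth of evaluable
patients in the responder group. Expression noise ($\sigma = 0.5$ log2
units), batch offsets (sd 0.5) and within-patient shift noise (sd 0.35)
are plausible for averaged log-ratio data. `t2_downshift = 0.5` (a
$\sqrt 2$-fold change) with 36 pairs yields a mean paired $t \approx 6$ —
a strong but not trivial planted effect. `hazard_frailty_sd = 4` makes the
patient-level hazard program dominate gene-level noise; this is
deliberate, because a per-gene screen estimates an attenuated slope when
the gene is a noisy surrogate for the patient-level signal
(classical errors-in-covariates), and the default keeps that attenuation
near 10–15% so single-gene estimates remain interpretable against the
planted $\beta = 0.8$. `baseline_hazard = 0.02`/month with a 60-month
uniform censoring horizon produces a 40–50% event rate among
residual-disease patients.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: intensity-dependent (non-additive) batch
artifacts; correlated gene-gene structure beyond the planted blocks
(real co-expression modules make effective test counts smaller than
nominal); informative missingness (arrays are dropped at random here,
while real TS availability correlates with tumor size); subtype switching
driven by cellularity change (simulated T2 profiles keep their centroid,
so concordance runs near 100%, unlike clinical serial cohorts);
non-proportional hazards; and measurement error correlated between time
points.

## Numerical choices

* Permutation tail counting uses a relative tolerance of $10^{-12}$ so
  exact sign-flip ties are included deterministically.
* BH adjustment delegates to `p.adjust(method = "BH")` over the
  non-missing entries (missing p-values pass through and do not count
  toward $m$); an independent step-up implementation is kept in the test
  suite as the oracle.
* Residualization asserts nothing about scale: residual batch means are
  zero to $10^{-10}$ and the operation is idempotent to the same
  tolerance (both tested).
* Monte-Carlo permutation streams are keyed to the user seed *and* the
  per-gene missingness pattern, so genes sharing a pattern share one null
  assignment matrix — reproducible regardless of gene order, and the main
  reason the matrix engines are fast (one `D S^T` multiply per pattern,
  chunked to ~128 MB blocks).
* `rate_percent()` rounds half away from zero; R's own `round()`
  half-to-even rule would print some small-cohort rates differently.

## Problem sizes in the shipped tests

The test suite runs the full default cohort (2000 genes, 48 patients,
10,000 permutations) once for recovery checks, 20 null cohorts for
false-discovery control, 20 seeded 100-patient cohorts for Cox recovery,
and a 10,000-gene exhaustive null (12 pairs, $2^{12}$ assignments) for
type-I error — about three minutes in total on one CPU; these sizes were
chosen to keep seed-to-seed variability well below the tested margins
while remaining comfortable for routine development.

## Known limitations

* The package tests features at the level of the supplied matrix; when a
  probe map is given, probe-level and gene-level significant counts can
  both be reported, but no probe-to-gene p-value combination is attempted.
* Survival screens fit one gene at a time; no multivariable signatures,
  penalized models, time-dependent covariates or proportionality
  diagnostics.
* Subtype calls depend entirely on the supplied centroid panel; no
  calibration, gene centering to a reference population, or prognostic
  scores.
* The enrichment universe is the tested-gene set; results are not
  comparable across analyses with different universes.
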