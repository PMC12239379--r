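---
title: "Models and methods: longitudinal methylation and trained immunity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: longitudinal methylation and trained immunity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcgmeth)
library(dplyr)
```

# Scope

`bcgmeth` implements an analysis pipeline for three-timepoint (baseline T0,
day 14, day 90) whole-blood DNA methylation cohorts measured around BCG
vaccination, together with stimulated cytokine readouts ("trained
immunity"), genotypes and auxiliary omics layers. The pipeline starts from a
normalized beta matrix; array-level processing (IDAT import, detection
p-values, probe filtering, quantile normalization) is upstream and out of
scope. Because real cohorts of this design are controlled-access, the
package ships a synthetic-cohort generator with a ground-truth ledger, and
every stage is validated against that ground truth.

# Measurement model and transforms

Methylation fractions (beta values) are modelled on the base-2 logit scale,
`M = log2(beta / (1 - beta))`, where array noise is closer to homoscedastic.
`beta_to_m()` clamps exact 0/1 to `eps = 1e-6` with a warning so the logit
stays finite; the inverse is exact to 1e-12 inside the clamped range.
Extreme outliers are masked per probe by the Tukey rule (below Q1 − 3·IQR or
above Q3 + 3·IQR, quartiles by the type-7 linear-interpolation convention;
strict inequalities, so constant probes are never masked). The rule is
applied once, as in standard EWAS QC. Note that it is *not* idempotent in
the strict sense: removing extremes changes the quartiles, so re-applying
the rule to masked data can mask further points. The package applies a
single pass and the tests assert the one-pass contract (every masked value
violates the fences computed from the data it was masked from).

# Cell composition

Whole-blood methylation is dominated by leukocyte composition.
`deconvolve_cells()` estimates per-sample fractions by reference-based
constrained projection: minimise ‖x − R f‖² subject to f ≥ 0 and Σf = 1,
where R holds mean beta values of marker probes per cell type. The simplex
constraint is imposed by non-negative least squares on a system augmented
with a heavily weighted (λ = 1000) row of ones, then renormalised; exact
mixtures are recovered to machine precision and mixtures with 0.02
beta-units of noise to a mean absolute error well under 0.05. The main
panel has six leukocyte types with a dominant neutrophil-like component; a
12-type panel can be supplied through the same solver for sensitivity
refits.

# Trained-immunity outcome

For each cytokine (TNF-α, IL-1β, IL-6, IFN-γ) the outcome is the log10 fold
change of stimulated production at T90 versus T0. `compute_ti()` applies,
in order: log10 ratio, additive batch correction (residuals of a one-way
fit on the assay batch, grand mean retained — the simplest faithful reading
of "correcting for batch effect"), and inverse-rank normal transformation.
The rank transform uses the Blom offset, `z = Φ⁻¹((r − 3/8)/(n + 1/4))`,
with average ranks for ties — the most common EWAS/GWAS convention; the
offset is configurable.

# Association models

* **Longitudinal EWAS** (`fit_mixed_ewas()`): per probe, a linear mixed
  model of M values on timepoint (unordered factor, T0 reference) with a
  random subject intercept (REML), adjusting for age, sex, plate and cell
  fractions (the first, reference cell type is dropped to keep the design
  full rank). The overall vaccination effect is a joint 2-df test of the
  T14 and T90 terms with Satterthwaite denominator degrees of freedom;
  pairwise contrasts refit on the two timepoints involved. Probes whose
  random-intercept variance collapses to the boundary are refitted by OLS
  with cluster-robust (subject) standard errors and flagged rather than
  silently dropped. Timepoint is coded as a factor, not a trend, because
  the response shapes of interest (transient versus persistent) are not
  monotone.
* **Baseline methylation vs trained immunity** (`fit_robust_ewas()`): Huber
  M-estimation (tuning constant 1.345, IRLS to 1e-8 or 50 iterations) of
  the normalized TI outcome on the probe's M value plus covariates, with
  the estimator's asymptotic standard errors and a t reference on residual
  degrees of freedom.
* **Methylation change (DNAm-C)** (`residualize_by_timepoint()` +
  `dnamc_association()`): because cell composition differs by timepoint,
  M values are first residualized on plate and cell fractions *within each
  timepoint*; per-subject differences of the residuals between two
  timepoints are then regressed (robustly) on TI with age and sex as
  covariates.
* **Multiplicity**: Benjamini–Hochberg within each scan (q < 0.05
  significant, p < 1e-5 suggestive); `compute_inflation()` reports the
  genomic inflation factor λ as a calibration diagnostic.
* **Sensitivity refits** (`sensitivity_refit()`): the same machinery with a
  12-type cell panel, added seasonality covariates (harmonic encoding
  `sin/cos(2π · day-of-year / 365.25)` — the annual phase, a documented
  stand-in since no exact encoding is canonical), or the age-over-30
  subgroup; reported as direction- and threshold-concordance with the base
  scan. Sex-stratified analyses are the same operations on sample-sheet
  subsets, verified by equality with manual subsetting.

# Genotype-linked inference

`qtl_scan()` performs matrix-style marginal regressions of phenotypes
(normalized TI, or per-probe DNAm-C) on SNP dosages after residualizing the
phenotype on age and sex (two-stage, matching the cytokine-QTL design);
t and p use n − 2 degrees of freedom on the residualized data and the scan
equals the per-pair OLS oracle to 1e-8. SNPs with p < 0.05 for both TI and
a DNAm-C probe define candidate triplets (`discover_triplets()`).

`fit_mediation()` is a from-first-principles quasi-Bayesian linear
mediation: OLS mediator and outcome models (no exposure–mediator
interaction, matching the stated model y = x + m + ε), parameter draws from
each fit's asymptotic normal, ACME = a·b per draw, ADE = c′, total =
ACME + ADE, percentile intervals, two-sided simulation p with the add-one
convention, and proportion mediated as the median of ACME/total (flagged
unstable when |total| < 2 SE). In the linear case the ACME point estimate
equals the product of coefficients up to Monte-Carlo error, and
ACME + ADE equals the total-effect OLS slope exactly at the coefficient
level.

`bidirectional_mediation()` runs both directions — D1: methylation change
mediates the genetic effect on TI; D2: TI mediates the genetic effect on
methylation change — and classifies by the two ACME p-values at 0.05. A
caveat the tests make explicit: in the linear-Gaussian setting both
directions share the same mediator–outcome partial correlation, so the
directions are distinguished only through the exposure→mediator versus
exposure→outcome(total) paths. Direction triage is therefore informative
when the mediator path is strong and the reverse total effect is near the
noise floor; the validation simulations use such an operating point
(a = 0.5, b = 0.4, c′ = 0, mediator noise sd 1.7, outcome noise sd 3.7,
n = 500), where the one-way generator is classified `unidirectional_D1` in
about 85% of runs.

`cis_window_enrichment()` extracts cytokine-QTL p-values of SNPs within
±250 kb (inclusive, 1-based coordinates) of a CpG list and compares them
with a size-matched random SNP set by a Kolmogorov–Smirnov test.

# Variance partitioning

`variance_explained()` follows a greedy screening scheme per layer:
candidate features are those with Spearman p < 0.05 against TI (for the
methylation layer, an externally supplied EWAS-significant CpG list is used
instead); within-layer collinearity is pruned by repeatedly visiting the
pair with the largest |Spearman ρ| > 0.4 (ties by feature id) and dropping
the member with the weaker TI association, until no pair exceeds the
threshold. The absolute value is used although the rule is often quoted
unsigned, because anti-correlated duplicates are equally collinear; the
iteration order is fixed to make the greedy rule deterministic. Explained
variance is the adjusted R² of the OLS fit on the pruned predictors; the
combined model concatenates each layer's pruned set without re-pruning
across layers. `randomization_null()` repeats the full select→prune→fit
procedure on B random feature draws of fixed size (k = 73, mirroring the
size of a typical protein panel) and reports an add-one empirical p.
`compute_prs()` builds a polygenic score as the weighted dosage sum, with
weights either supplied or derived from marginal QTL betas at p < 0.05 on a
training split.

# The synthetic cohort

`generate_cohort()` draws, per subject: age, sex, BMI, smoking, plate
assignments and a T0 collection date uniform over a calendar year (T14/T90
follow at +14/+90 days). Cell fractions come from a Dirichlet whose largest
mean belongs to a neutrophil-like component, with a small timepoint drift
so composition genuinely confounds time. Methylation is simulated on the M
scale: per-probe cell-type reference profiles are mixed linearly in M
space, then subject intercepts (sd 0.7), probe-specific plate shifts
(sd 0.3) and residual noise (sd 1.0) are added, and betas are obtained by
the inverse logit — so beta values are strictly inside (0, 1) and the
beta/M transform is exact. Mixing on the M scale (rather than mixing betas
and taking logits) keeps each probe's M value exactly linear in the
fractions, which is what the covariate-adjusted association models assume;
with nonlinear mixing the null scans showed visible miscalibration, so the
linear-in-M construction is the deliberate choice.

Effect blocks with ledgered ground truth: the four trajectory shapes
(±d14/±d90 in M units at T14/T90; defaults 1.0), sex-shift probes, optional
seasonal probes, baseline probes feeding TI, and mediation triplets
generated literally as `m_change = a·g + ε₁` added to the probe's T90
values and `ti += b·m_change + c′·g` (centred so the cytokine fold changes
stay realistic; coefficients untouched). The TI outcome is a
variance-budgeted sum of layer latents — methylation (a weighted combination
of the spiked baseline probes), metabolites, proteins, genetics (a weighted
dosage sum) — scaled to 0.4 sd on the log10 fold-change scale, plus assay
batch shifts that `compute_ti()` removes. The effect-size defaults are free
parameters of the simulation (real per-CpG effect sizes are not published
for this design); they were set once to values that make the scans'
operating characteristics visible at desk scale and are not calibrated to
any cohort. `generate_replication()` redraws a smaller two-timepoint cohort
(default n = 17) under the same ledger, so trajectory effect directions are
shared and noise is fresh.

What the generator does *not* emulate: probe-probe correlation along the
genome, linkage disequilibrium between SNPs, cell-type interactions,
non-Gaussian M-value noise, and missingness patterns other than those
induced by outlier masking. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artefact of real arrays.

# Validation design and problem sizes

The test suite validates: exact transforms; oracle equivalence (BH versus
brute-force step-up for all inputs up to 10 p-values; Fisher's exact test
versus full hypergeometric enumeration for every 2×2 table with N ≤ 30;
the QTL scan versus per-pair OLS); null calibration of all four scans on
zero-effect cohorts of 2000 probes × 100 subjects, with p-values pooled
across seeded replicate cohorts (3 for the mixed scan, 10 for the robust
and DNAm-C scans) because the genomic λ of a single 2000-probe scan has a
Monte-Carlo sd of about 0.05; effect recovery (trajectory classes exact on
noiseless means; ≥95% power at Δ = 1 M-unit, n = 200); deconvolution
recovery; mediation recovery including type-I control (200 replicates) and
direction triage (50 runs); variance-fraction recovery (0.30/0.10 within
±0.08 at n = 300 over 20 replicates) with a B = 200 randomization null;
and byte-identical reproduction of all written tables under a fixed seed.
These problem sizes were chosen so the full suite runs on a single CPU in
minutes while keeping each check's Monte-Carlo error well inside its
tolerance.

A note on the "noiseless" mediation limit: the product-of-coefficients
identity is exercised with noise on the mediator and a (near-)noiseless
outcome. If both noises shrink together, exposure and mediator become
collinear in the outcome model and b is no longer identified — its sampling
error stays finite however small the noise — so only the
noiseless-outcome parameterization attains ACME → a·b exactly.

# Known limitations

* The robust-regression standard errors are the IRLS asymptotic errors;
  inference is approximate at small n.
* Direction triage in linear-Gaussian mediation is only weakly identified
  (see above); `bidirectional` calls on strong signals are expected
  behaviour, not errors.
* The variance-partition screening inflates adjusted R² slightly through
  feature selection (visible as a small positive bias on the metabolite
  layer); the randomization null quantifies this under the same selection.
* The CLI-style entry points are deliberately omitted: the package is an
  analysis library, and the exported functions plus this vignette are the
  interface.
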