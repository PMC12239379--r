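# bcgmeth

Longitudinal DNA methylation and trained-immunity analysis for BCG
vaccination cohorts.

BCG vaccination induces *trained immunity* — a durable boost of innate
cytokine responses — and leaves traces in whole-blood DNA methylation. This
package implements, as a tested and reusable R pipeline, the statistical
machinery needed to study that process in a three-timepoint design
(baseline T0, day 14, day 90):

* **Longitudinal EWAS** — per-CpG linear mixed models of M values
  (`M = log2(β/(1−β))`) on timepoint with a random subject intercept,
  adjusting for age, sex, plate and estimated cell composition; overall
  2-df tests and pairwise contrasts (T14−T0, T90−T0, T90−T14).
* **Trajectory taxonomy** — classification of responsive CpGs by the sign
  pattern of their beta-value changes (`down_down`, `down_up`, `up_down`,
  `up_up`) and Fisher-exact enrichment against baseline methylation state.
* **Trained-immunity association** — the TI outcome per cytokine is the
  inverse-rank-normalized, batch-corrected `log10(c_T90/c_T0)` of
  stimulated production; robust (Huber) regressions link it to baseline
  methylation and to covariate-residualized methylation *changes* (DNAm-C).
* **Variance partitioning** — Spearman screening (p < 0.05), greedy
  collinearity pruning (|ρ| > 0.4), adjusted R² per omics layer and
  combined, with a randomization null over random feature sets.
* **Genotype-linked inference** — a matrix-style cytokine-QTL scan,
  ±250 kb cis-window enrichment, and bidirectional quasi-Bayesian causal
  mediation (ACME, proportion mediated) of SNP effects through methylation
  change versus through trained immunity, with direction triage.
* **Synthetic cohorts** — a generator that emulates the full design
  (cell-composition confounding, plate batches, seasonal covariates,
  spiked trajectory/TI/mediation effects) and returns a ground-truth
  ledger, so every stage is testable without controlled-access data.

Everything is tidyverse-native: analysis functions take a matrix plus a
sample-sheet data frame and return tibbles; results support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Simulate a cohort with known spiked effects, run the T90−T0 EWAS, and
inspect the top hits:

```r
library(bcgmeth)
library(dplyr)

cfg    <- cohort_config(n_subjects = 120, n_probes = 500, seed = 42)
cohort <- generate_cohort(cfg)
mvals  <- beta_to_m(cohort$betas)

ewas <- fit_mixed_ewas(mvals, cohort$samples, contrast = "T90-T0",
                       cell_fractions = cohort$cell_fractions)
glance(ewas)
#> # A tibble: 1 × 5
#>   model_tag    n_probes n_fdr_significant n_suggestive lambda
#>   <chr>           <int>             <int>        <int>  <dbl>
#> 1 mixed_T90-T0      500                45           41   1.30

tidy(ewas) |> arrange(p) |> head(4) |> select(probe_id, estimate, se, p, q)
#> # A tibble: 4 × 5
#>   probe_id  estimate    se        p        q
#>   <chr>        <dbl> <dbl>    <dbl>    <dbl>
#> 1 cg0000023   -1.23  0.127 1.25e-16 6.23e-14
#> 2 cg0000009   -1.21  0.129 8.79e-16 2.20e-13
#> 3 cg0000030   -1.04  0.116 6.58e-15 1.10e-12
#> 4 cg0000008   -0.958 0.112 7.22e-14 9.03e-12
```

All four top probes are spiked time-effect probes from the cohort's truth
ledger (`cohort$ledger$trajectory`); the estimates recover the simulated
−1 M-unit changes, and λ = 1.30 reflects the genuine signal among 500
probes (40 carry time effects). The 45 FDR hits versus 41 suggestive hits
show the two thresholds in action.

Causal mediation of a genetic effect through methylation change:

```r
set.seed(9)
n     <- 500
snp   <- rbinom(n, 2, 0.3)                  # dosage, MAF 0.3
dnamc <- 0.5 * snp + rnorm(n, 0, 0.3)       # methylation change
ti    <- 0.4 * dnamc + 0.3 * snp + rnorm(n, 0, 0.3)

med <- fit_mediation(snp, dnamc, ti, n_sims = 1000, seed = 7)
tidy(med)
#> # A tibble: 4 × 5
#>   term          estimate conf_low conf_high  p_value
#>   <chr>            <dbl>    <dbl>     <dbl>    <dbl>
#> 1 acme             0.162    0.119     0.209  0.00200
#> 2 ade              0.310   NA        NA      0.00200
#> 3 total            0.472   NA        NA      0.00200
#> 4 prop_mediated    0.342   NA        NA     NA
```

The ACME estimate recovers the generative indirect effect
(a·b = 0.5 × 0.4 = 0.2, here attenuated only by sampling noise), ADE the
direct path (0.3), and the proportion mediated is near the true
0.2/0.5 = 0.4. `bidirectional_mediation()` runs both causal directions and
classifies the triplet.

See `vignettes/methods.Rmd` for the models, their assumptions, the
synthetic-cohort construction, and the validation design.

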