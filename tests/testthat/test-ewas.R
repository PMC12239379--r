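test_that("BH adjustment matches the hand-computed and brute-force step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  # NA placement preserved
  q <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  set.seed(10)
  for (i in 1:50) {
    p <- round(runif(sample(1:10, 1)), 3)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("inflation factor behaves as a calibrated median statistic", {
  expect_equal(compute_inflation(c(rep(0.5, 100))) |> suppressWarnings(), 1)
  set.seed(2)
  p <- runif(1e5)
  expect_equal(compute_inflation(p), 1, tolerance = 0.02)
  expect_gt(compute_inflation(p / 2), 1)      # uniformly smaller p inflates
  expect_error(compute_inflation(runif(50)), ">= 100")
  expect_warning(compute_inflation(rep(0.2, 200)), "degenerate")
})

test_that("seasonality terms encode the annual phase deterministically", {
  s1 <- seasonality_terms(as.Date("2019-03-01"))
  s2 <- seasonality_terms(as.Date("2019-09-01"))   # ~6 months later
  expect_lt(s1$season_sin * s2$season_sin, 0)
  expect_equal(seasonality_terms(as.Date("2019-05-20")),
               seasonality_terms(as.Date("2023-05-20")))
  days <- as.Date("2019-01-01") + 0:364
  expect_lt(abs(mean(seasonality_terms(days)$season_sin)), 0.02)
  expect_true(is.na(seasonality_terms(as.Date(NA))$season_sin))
})

test_that("per-timepoint residualization is orthogonal to its covariates", {
  co <- small_cohort()
  mv <- beta_to_m(co$betas)
  res <- residualize_by_timepoint(mv, co$samples,
                                  cell_fractions = co$cell_fractions)
  frame <- dplyr::left_join(co$samples, co$cell_fractions, by = "sample_id")
  for (tp in c("T0", "T90")) {
    ix <- frame$timepoint == tp
    cf <- as.matrix(frame[ix, setdiff(names(co$cell_fractions),
                                      c("sample_id", "Neu"))])
    for (pb in rownames(mv)[1:5]) {
      expect_lt(max(abs(cor(res[pb, frame$sample_id[ix]], cf))), 1e-10)
    }
  }
  # values exactly linear in covariates leave zero residuals
  n <- sum(frame$timepoint == "T0")
  lin <- matrix(2 + 3 * frame$age[frame$timepoint == "T0"], 1,
                dimnames = list("lin", frame$sample_id[frame$timepoint ==
                                                         "T0"]))
  r_lin <- residualize_by_timepoint(lin,
                                    co$samples[co$samples$timepoint == "T0", ],
                                    covariates = "age")
  expect_lt(max(abs(r_lin)), 1e-8)
  # covariate-free residualization just centres
  r_c <- residualize_by_timepoint(lin,
                                  co$samples[co$samples$timepoint == "T0", ],
                                  covariates = character(0))
  expect_equal(drop(r_c), drop(lin - mean(lin)), ignore_attr = TRUE)
})

test_that("mixed-model contrast equals the paired mean difference when balanced", {
  set.seed(12)
  ns <- 30
  subj <- sprintf("s%02d", 1:ns)
  samples <- tibble::tibble(
    sample_id = c(paste0(subj, "_T0"), paste0(subj, "_T90")),
    subject_id = rep(subj, 2),
    timepoint = rep(c("T0", "T90"), each = ns)
  )
  mv <- matrix(rnorm(2 * ns * 10), 10,
               dimnames = list(paste0("cg", 1:10), samples$sample_id))
  mv <- mv + matrix(rep(rnorm(ns, 0, 1), each = 10), 10, 2 * ns)
  res <- fit_mixed_ewas(mv, samples, contrast = "T90-T0",
                        covariates = character(0))
  paired <- rowMeans(mv[, samples$timepoint == "T90"]) -
    rowMeans(mv[, samples$timepoint == "T0"])
  expect_equal(res$estimate, unname(paired), tolerance = 1e-6)
})

test_that("mixed EWAS detects a strong spiked time effect with correct sign", {
  co <- cached_cohort("spiked", cohort_config(
    n_subjects = 60, n_probes = 100,
    trajectory = list(n_per_class = 3, d14 = 1, d90 = 1),
    n_ti_probes = 0, n_sex_probes = 0,
    mediation = list(n_triplets = 0, a = 0, b = 0, c_prime = 0,
                     noise1 = 0.3),
    seed = 14))
  mv <- beta_to_m(co$betas)
  led <- co$ledger$trajectory
  res <- fit_mixed_ewas(mv, co$samples, contrast = "T90-T0",
                        cell_fractions = co$cell_fractions,
                        probes = led$probe_id)
  expect_true(all(res$p < 1e-3))
  expect_equal(sign(res$estimate), sign(led$d90))
})

test_that("stratified fits equal fits on manually subset inputs", {
  co <- small_cohort()
  mv <- beta_to_m(co$betas)
  fem <- co$samples[co$samples$sex == "F", ]
  pr <- rownames(mv)[1:5]
  full_mat <- fit_mixed_ewas(mv, fem, contrast = "T90-T0",
                             covariates = c("age", "plate"), probes = pr)
  sub_mat <- fit_mixed_ewas(mv[, fem$sample_id], fem, contrast = "T90-T0",
                            covariates = c("age", "plate"), probes = pr)
  expect_equal(tidy(full_mat), tidy(sub_mat))
})

test_that("robust EWAS agrees with OLS on clean Gaussian data", {
  set.seed(33)
  n <- 200
  subj <- sprintf("s%03d", 1:n)
  samples <- tibble::tibble(sample_id = paste0(subj, "_T0"),
                            subject_id = subj, timepoint = "T0",
                            age = rnorm(n, 30, 8))
  mv <- matrix(rnorm(60 * n), 60,
               dimnames = list(paste0("cg", 1:60), samples$sample_id))
  beta_true <- rnorm(60, 0, 0.5)
  ti_tbl <- tibble::tibble(subject_id = subj, ti_norm = 0)
  rel <- ols <- numeric(60)
  for (i in 1:60) {
    y <- beta_true[i] * mv[i, ] + rnorm(n, 0, 0.5)
    ti_tbl$ti_norm <- y
    rr <- fit_robust_ewas(mv, ti_tbl, samples, covariates = "age",
                          probes = rownames(mv)[i])
    ols[i] <- coef(lm(y ~ mv[i, ] + samples$age))[2]
    rel[i] <- rr$estimate
  }
  expect_lt(sqrt(mean((rel - ols)^2)) / sqrt(mean(ols^2)), 0.02)
})

test_that("robust regression resists a gross outlier better than OLS", {
  set.seed(44)
  wins <- replicate(40, {
    n <- 120
    x <- rnorm(n)
    x[1] <- max(abs(x)) + 2        # high-leverage point...
    y <- 0.5 * x + rnorm(n, 0, 0.5)
    y[1] <- y[1] + 10 * 0.5        # ...with a 10 sigma outcome outlier
    subj <- sprintf("s%03d", 1:n)
    samples <- tibble::tibble(sample_id = paste0(subj, "_T0"),
                              subject_id = subj, timepoint = "T0")
    mv <- matrix(x, 1, dimnames = list("cg1", samples$sample_id))
    rr <- fit_robust_ewas(mv, tibble::tibble(subject_id = subj, ti_norm = y),
                          samples, covariates = character(0))
    b_ols <- coef(lm(y ~ x))[2]
    abs(rr$estimate - 0.5) < abs(b_ols - 0.5)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("constant probes are flagged, not fitted", {
  subj <- sprintf("s%02d", 1:30)
  samples <- tibble::tibble(sample_id = paste0(subj, "_T0"),
                            subject_id = subj, timepoint = "T0")
  mv <- matrix(1.5, 1, 30, dimnames = list("cg1", samples$sample_id))
  rr <- fit_robust_ewas(mv, tibble::tibble(subject_id = subj,
                                           ti_norm = rnorm(30)),
                        samples, covariates = character(0))
  expect_equal(rr$model, "constant predictor")
  expect_true(is.na(rr$p))
})

test_that("DNAm-C association recovers a spiked slope and rejects constants", {
  co <- small_cohort()
  mv <- beta_to_m(co$betas)
  res <- residualize_by_timepoint(mv, co$samples,
                                  cell_fractions = co$cell_fractions)
  subj <- unique(co$samples$subject_id)
  dn <- res[, paste0(subj, "_T90")] - res[, paste0(subj, "_T0")]
  set.seed(7)
  spiked <- rownames(mv)[150]
  ti_val <- 0.8 * scale(dn[spiked, ])[, 1] + rnorm(length(subj), 0, 0.6)
  ti_tbl <- tibble::tibble(subject_id = subj,
                           ti_norm = inverse_rank_normalize(ti_val))
  out <- dnamc_association(res, "T90-T0", ti_tbl, co$samples,
                           probes = c(spiked, rownames(mv)[151:155]))
  expect_lt(out$p[out$probe_id == spiked], 1e-6)
  expect_gt(out$estimate[out$probe_id == spiked], 0)
  # identical residuals at both timepoints: constant predictor
  res_const <- res
  res_const[, paste0(subj, "_T90")] <- res_const[, paste0(subj, "_T0")]
  expect_error(dnamc_association(res_const, "T90-T0", ti_tbl, co$samples),
               "constant predictor")
})

test_that("sensitivity refits report concordance against the base model", {
  co <- cached_cohort("spiked", cohort_config(
    n_subjects = 60, n_probes = 100,
    trajectory = list(n_per_class = 3, d14 = 1, d90 = 1),
    n_ti_probes = 0, n_sex_probes = 0,
    mediation = list(n_triplets = 0, a = 0, b = 0, c_prime = 0,
                     noise1 = 0.3),
    seed = 14))
  mv <- beta_to_m(co$betas)
  led <- co$ledger$trajectory
  base <- fit_mixed_ewas(mv, co$samples, contrast = "T90-T0",
                         cell_fractions = co$cell_fractions,
                         probes = led$probe_id)
  # a variant with identical design reproduces the base exactly
  same <- sensitivity_refit(mv, co$samples, base, variant = "cells12",
                            contrast = "T90-T0",
                            cell_fractions = co$cell_fractions,
                            cell_fractions_12 = co$cell_fractions,
                            probes = led$probe_id)
  expect_equal(same$concordance$frac_same_direction, 1)
  expect_equal(tidy(same$results), tidy(base))
  # seasonality covariates leave season-independent effects in place
  seas <- sensitivity_refit(mv, co$samples, base, variant = "seasonality",
                            contrast = "T90-T0",
                            cell_fractions = co$cell_fractions,
                            probes = led$probe_id)
  expect_equal(seas$concordance$frac_same_direction, 1)
  # age subgroup runs on fewer samples
  sub <- sensitivity_refit(mv, co$samples, base, variant = "age_over_30",
                           contrast = "T90-T0",
                           cell_fractions = co$cell_fractions,
                           probes = led$probe_id)
  expect_lt(max(sub$results$n_used), max(tidy(base)$n_used))
  old <- co$samples
  old$age <- 20
  expect_error(sensitivity_refit(mv, old, base, variant = "age_over_30",
                                 contrast = "T90-T0",
                                 probes = led$probe_id),
               "empty")
})
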