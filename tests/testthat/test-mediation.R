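test_that("QTL scan reproduces the per-pair OLS fit", {
  set.seed(23)
  ns <- 80
  subj <- paste0("s", 1:ns)
  g <- matrix(rbinom(20 * ns, 2, runif(20, 0.1, 0.5)), 20, byrow = FALSE,
              dimnames = list(paste0("rs", 1:20), subj))
  ph <- matrix(rnorm(ns * 3), ns, 3,
               dimnames = list(subj, paste0("y", 1:3)))
  scan <- qtl_scan(g, ph)
  for (i in sample(nrow(scan), 20)) {
    row <- scan[i, ]
    fit <- summary(lm(ph[, row$phenotype] ~ g[row$snp_id, ]))$coefficients
    expect_equal(row$beta, fit[2, 1], tolerance = 1e-8)
    expect_equal(row$t, fit[2, 3], tolerance = 1e-8)
    expect_equal(row$p, fit[2, 4], tolerance = 1e-8)
  }
  # phenotype equal to the dosage: slope one, floor p
  ph2 <- matrix(as.numeric(g[1, ]), ns, 1, dimnames = list(subj, "same"))
  r <- qtl_scan(g[1, , drop = FALSE], ph2)
  expect_equal(r$beta, 1)
  expect_lt(r$p, 1e-100)
  # monomorphic SNP flagged
  g2 <- rbind(g, fixed = rep(1, ns))
  r2 <- qtl_scan(g2, ph)
  expect_true(all(is.na(r2$p[r2$snp_id == "fixed"])))
  expect_true(all(r2$reason[r2$snp_id == "fixed"] == "monomorphic"))
})

test_that("age/sex residualization changes the scan as a two-stage fit", {
  set.seed(24)
  ns <- 100
  subj <- paste0("s", 1:ns)
  samples <- tibble::tibble(sample_id = paste0(subj, "_T0"),
                            subject_id = subj, timepoint = "T0",
                            age = rnorm(ns, 30, 8),
                            sex = sample(c("M", "F"), ns, TRUE))
  g <- matrix(rbinom(ns, 2, 0.4), 1, dimnames = list("rs1", subj))
  y <- 2 * samples$age + rnorm(ns)
  ph <- matrix(y, ns, 1, dimnames = list(subj, "y"))
  scan <- qtl_scan(g, ph, samples = samples)
  X <- model.matrix(~ age + sex, data = samples)
  y_res <- resid(lm.fit(X, y))
  oracle <- summary(lm(y_res ~ g[1, ]))$coefficients
  expect_equal(scan$beta, oracle[2, 1], tolerance = 1e-8)
  expect_equal(scan$p, oracle[2, 4], tolerance = 1e-8)
})

test_that("triplet discovery crosses the two scans at the threshold", {
  qtl_ti <- tibble::tibble(snp_id = c("rs1", "rs2", "rs3"),
                           phenotype = "IFNg",
                           p = c(0.04, 0.03, 0.5))
  qtl_dn <- tibble::tibble(snp_id = c("rs1", "rs2", "rs2"),
                           phenotype = c("cg1", "cg1", "cg2"),
                           p = c(0.2, 0.01, 0.03))
  tri <- discover_triplets(qtl_ti, qtl_dn)
  # rs1 qualifies for TI only; rs2 for both, with two probes
  expect_equal(tri$snp_id, c("rs2", "rs2"))
  expect_equal(tri$probe_id, c("cg1", "cg2"))
  expect_equal(nrow(discover_triplets(qtl_ti, qtl_dn, alpha = 0)), 0)
})

test_that("ACME equals the product of coefficients in the linear case", {
  set.seed(25)
  n <- 300
  x <- rbinom(n, 2, 0.3)
  m <- 0.5 * x + rnorm(n, 0, 0.4)
  y <- 0.4 * m + 0.3 * x + rnorm(n, 0, 0.4)
  a_hat <- coef(lm(m ~ x))[2]
  fit_y <- lm(y ~ x + m)
  b_hat <- coef(fit_y)["m"]
  cp_hat <- coef(fit_y)["x"]
  med <- fit_mediation(x, m, y, n_sims = 1e5, seed = 2)
  expect_equal(med$acme, unname(a_hat * b_hat),
               tolerance = 1e-2 * abs(a_hat * b_hat))
  # ACME + ADE recovers the total-effect OLS slope (coefficient identity)
  total_ols <- coef(lm(y ~ x))[2]
  expect_equal(unname(a_hat * b_hat + cp_hat), unname(total_ols),
               tolerance = 1e-6)
  expect_equal(med$total, unname(total_ols), tolerance = 0.01)
})

test_that("noiseless-outcome mediation gives ACME 0.20 and full mediation", {
  set.seed(26)
  n <- 1000
  x <- rbinom(n, 2, 0.3)
  m <- 0.5 * x + rnorm(n, 0, 0.3)
  y <- 0.4 * m + rnorm(n, 0, 1e-8)
  med <- fit_mediation(x, m, y, n_sims = 2000, seed = 3)
  expect_equal(med$acme, 0.2, tolerance = 0.02)
  expect_equal(med$prop_mediated, 1, tolerance = 0.001)
  expect_lt(med$acme_p, 0.01)
})

test_that("mediation guards its preconditions", {
  x <- rbinom(20, 2, 0.3)
  expect_error(fit_mediation(x, rnorm(20), rnorm(20)), ">= 30")
  x2 <- rbinom(50, 2, 0.3)
  expect_error(fit_mediation(x2, m = x2, y = rnorm(50)), "singular")
})

test_that("direction triage labels a one-way mediation as D1", {
  # direction is identifiable when the exposure drives the mediator
  # strongly while the reverse-direction exposure path (the total effect
  # on the outcome) sits at the noise floor
  set.seed(27)
  n <- 500
  x <- rbinom(n, 2, 0.3)
  dnamc <- 0.5 * x + rnorm(n, 0, 1.7)
  ti <- 0.4 * dnamc + rnorm(n, 0, 3.7)
  bm <- bidirectional_mediation(x, dnamc, ti, n_sims = 500, seed = 5)
  expect_equal(attr(bm, "classification"), "unidirectional_D1")
  expect_equal(nrow(bm), 2)
  expect_lt(bm$acme_p[bm$direction == "D1"], 0.05)
})

test_that("cis-window extraction uses inclusive 1-based bounds", {
  cpgs <- tibble::tibble(probe_id = "cg1", chromosome = "1",
                         position = 1000000L)
  snps <- tibble::tibble(
    snp_id = c("in_lo", "out_lo", "in_hi", "out_hi", "other_chr"),
    chromosome = c("1", "1", "1", "1", "2"),
    position = c(750000L, 749999L, 1250000L, 1250001L, 1000000L)
  )
  qtl <- tibble::tibble(snp_id = snps$snp_id, p = runif(5))
  out <- cis_window_enrichment(cpgs, snps, qtl, window = 250000, seed = 1)
  expect_setequal(out$cis$snp_id, c("in_lo", "in_hi"))
  far <- tibble::tibble(probe_id = "cg1", chromosome = "9",
                        position = 5L)
  expect_error(cis_window_enrichment(far, snps, qtl), "no SNP within")
})

test_that("spiked cis QTL signal separates from the random background", {
  set.seed(28)
  n_snp <- 400
  snps <- tibble::tibble(snp_id = paste0("rs", 1:n_snp),
                         chromosome = rep(c("1", "2"), each = n_snp / 2),
                         position = rep(seq(1e5, 2e7, length.out = n_snp / 2),
                                        2) |> as.integer())
  # CpGs sit on chromosome 1; their neighbouring SNPs carry small p
  cpgs <- tibble::tibble(probe_id = paste0("cg", 1:10), chromosome = "1",
                         position = as.integer(seq(2e6, 1.8e7,
                                                   length.out = 10)))
  cis_true <- vapply(seq_len(n_snp), function(i) {
    snps$chromosome[i] == "1" &
      any(abs(cpgs$position - snps$position[i]) <= 250000)
  }, logical(1))
  qtl <- tibble::tibble(snp_id = snps$snp_id,
                        p = ifelse(cis_true, rbeta(n_snp, 0.3, 4),
                                   runif(n_snp)))
  out <- cis_window_enrichment(cpgs, snps, qtl, seed = 2)
  expect_lt(out$ks$p, 0.01)
})
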