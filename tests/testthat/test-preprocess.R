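test_that("beta/M transform hits known values and is an exact inverse", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)            # antisymmetry around 0.5
  grid <- seq(1e-5, 1 - 1e-5, length.out = 500)
  expect_lt(max(abs(m_to_beta(beta_to_m(grid)) - grid)), 1e-12)
  expect_error(beta_to_m(1.2), "outside")
  expect_error(beta_to_m(-0.1), "outside")
  expect_warning(m0 <- beta_to_m(c(0, 1)), "clamped")
  expect_true(all(is.finite(m0)))
  # matrices keep shape and dimnames
  mat <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(dimnames(beta_to_m(mat)), dimnames(mat))
  expect_true(is.na(beta_to_m(NA)))
})

test_that("Tukey masking follows the 3-IQR fences and is idempotent", {
  res <- tukey_mask(c(1, 2, 3, 4, 100))
  expect_equal(which(res$mask), 5L)           # Q1=2, Q3=4, fence 4+3*2=10
  expect_equal(res$values[1:4], c(1, 2, 3, 4))
  # constant vector: IQR 0, strict inequality leaves everything
  expect_equal(sum(tukey_mask(rep(2, 10))$mask), 0)
  # clean symmetric data untouched
  expect_equal(sum(tukey_mask(c(-2, -1, 0, 1, 2))$mask), 0)
  expect_error(tukey_mask(rep(NA_real_, 5)), "all values missing")
  expect_error(tukey_mask(c(1, 2, 3)), ">= 4")
  # re-masking never un-masks, and every masked value violates the
  # fences computed on the data it was masked from
  set.seed(5)
  for (i in 1:20) {
    x <- c(rnorm(30), rnorm(2, 0, 50))
    r1 <- tukey_mask(x)
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    lo <- q[1] - 3 * (q[2] - q[1])
    hi <- q[2] + 3 * (q[2] - q[1])
    expect_true(all(x[r1$mask] < lo | x[r1$mask] > hi))
    expect_true(all(x[!r1$mask] >= lo & x[!r1$mask] <= hi))
    r2 <- tukey_mask(r1$values)
    expect_true(all(is.na(r2$values[r1$mask])))
  }
})

test_that("matrix-level masking only touches probes with enough data", {
  m <- rbind(a = c(1, 2, 3, 4, 100), b = c(1, NA, NA, 2, 3))
  out <- mask_outliers(m)
  expect_true(is.na(out["a", 5]))
  expect_equal(out["b", ], m["b", ])          # < 4 values: untouched
})

test_that("inverse-rank normalization is a rank-preserving Blom transform", {
  z <- inverse_rank_normalize(c(10, 2, 5))
  expect_equal(z[3], 0)                        # middle of 3 maps to 0
  expect_equal(z[1], -z[2])
  z2 <- inverse_rank_normalize(c(1, 1, 3, 7))
  expect_equal(z2[1], z2[2])                   # ties share output
  set.seed(3)
  x <- rexp(50)
  expect_equal(suppressWarnings(
    cor(x, inverse_rank_normalize(x), method = "spearman")), 1)
  expect_error(inverse_rank_normalize(rep(3, 10)), "identical")
  xna <- c(2, NA, 1, 5)
  expect_true(is.na(inverse_rank_normalize(xna)[2]))
})

test_that("cell deconvolution recovers mixtures of reference profiles", {
  set.seed(8)
  R <- matrix(runif(60 * 6, 0.05, 0.95), 60, 6,
              dimnames = list(sprintf("p%02d", 1:60), paste0("ct", 1:6)))
  f_true <- t(vapply(1:20, function(i) {
    g <- rgamma(6, 2)
    g / sum(g)
  }, numeric(6)))
  X <- R %*% t(f_true)
  colnames(X) <- paste0("s", 1:20)
  est <- deconvolve_cells(X, R)
  expect_lt(max(abs(as.matrix(est[, -1]) - f_true)), 1e-6)
  expect_equal(rowSums(as.matrix(est[, -1])), rep(1, 20), tolerance = 1e-8)
  # pure cell type gives an indicator vector
  pure <- matrix(R[, 3], ncol = 1, dimnames = list(rownames(R), "pure"))
  est_pure <- as.matrix(deconvolve_cells(pure, R)[, -1])
  expect_equal(unname(est_pure[1, ]), c(0, 0, 1, 0, 0, 0), tolerance = 1e-6)
  # invariant to reference column order up to label permutation
  perm <- c(4, 1, 6, 2, 5, 3)
  est_perm <- deconvolve_cells(X, R[, perm])
  expect_equal(as.matrix(est_perm[, -1]),
               as.matrix(est[, -1])[, perm, drop = FALSE],
               tolerance = 1e-6, ignore_attr = TRUE)
  # rank-deficient reference rejected
  R_bad <- R
  R_bad[, 2] <- R_bad[, 1]
  expect_error(deconvolve_cells(X, R_bad), "rank-deficient")
  expect_error(deconvolve_cells(X[1:10, ], R), "absent")
})

test_that("trained-immunity computation: log ratio, batch removal, ranks", {
  tbl <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    cytokine = "IFNg",
    conc_T0 = c(10, 50, 20, 40),
    conc_T90 = c(100, 50, 60, 10)
  )
  ti <- compute_ti(tbl)
  expect_equal(ti$ti_raw[ti$subject_id == "a"], 1)      # log10(10)
  expect_equal(ti$ti_raw[ti$subject_id == "b"], 0)
  # unit invariance: common positive rescaling of a pair
  tbl2 <- tbl
  tbl2$conc_T0 <- tbl2$conc_T0 * 7.3
  tbl2$conc_T90 <- tbl2$conc_T90 * 7.3
  expect_equal(compute_ti(tbl2)$ti_raw, ti$ti_raw)
  # additive batch shifts on the log scale are removed
  set.seed(4)
  n <- 40
  base <- rnorm(n, 0, 0.4)
  batch <- rep(c("B1", "B2"), each = n / 2)
  shift <- ifelse(batch == "B1", 0.5, -0.3)
  tbl3 <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                         cytokine = "IL6",
                         conc_T0 = 100,
                         conc_T90 = 100 * 10^(base + shift),
                         batch = batch)
  ti3 <- compute_ti(tbl3)
  gm <- mean(ti3$ti_corrected)
  for (b in c("B1", "B2")) {
    expect_equal(mean(ti3$ti_corrected[batch == b]), gm, tolerance = 1e-10)
  }
  # errors and drops
  tbl_bad <- tbl
  tbl_bad$conc_T0[2] <- -1
  expect_error(compute_ti(tbl_bad), "nonpositive")
  tbl_na <- tbl
  tbl_na$conc_T90[3] <- NA
  expect_message(out <- compute_ti(tbl_na), "dropping 1")
  expect_equal(nrow(out), 3)
})

test_that("PC-covariate scan finds an injected driver and sums variance", {
  set.seed(21)
  n <- 40
  driver <- rnorm(n)
  m <- matrix(rnorm(300 * n, sd = 0.3), 300, n)
  m[1:100, ] <- m[1:100, ] + outer(rnorm(100, 0, 2), driver)
  colnames(m) <- paste0("s", 1:n)
  covs <- tibble::tibble(sample_id = colnames(m), drv = driver,
                         noise = rnorm(n))
  sc <- pca_covariate_scan(m, covs, k = 5)
  drv_rows <- sc[sc$covariate == "drv", ]
  expect_equal(which.min(drv_rows$p), 1L)     # PC1 carries the driver
  expect_lt(drv_rows$p[1], 1e-10)
  # full-rank decomposition captures all variance
  sc_full <- pca_covariate_scan(m, covs, k = n - 1)
  expect_equal(attr(sc_full, "cum_var"), 1, tolerance = 1e-8)
  # constant covariate: NA with warning
  covs$flat <- 1
  expect_warning(sc2 <- pca_covariate_scan(m, covs, k = 3), "constant")
  expect_true(all(is.na(sc2$p[sc2$covariate == "flat"])))
})
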