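#' Fast marginal QTL scan
#'
#' Associates every SNP dosage with every phenotype by simple linear
#' regression computed through standardized cross-products (matrix-QTL
#' style). Phenotypes are first residualized on age and sex (two-stage:
#' covariates are regressed out of the phenotype before the scan); t and p
#' use `n - 2` degrees of freedom on the residualized data.
#'
#' @param dosages SNPs x subjects dosage matrix.
#' @param phenotypes Subjects x phenotypes numeric matrix (rownames =
#'   subject ids matching `colnames(dosages)`).
#' @param samples Optional sample sheet supplying `age` and `sex` per
#'   subject for residualization; `NULL` skips residualization.
#' @param covariates Columns regressed out of the phenotypes (default
#'   `c("age", "sex")`).
#' @return Tibble: `snp_id`, `phenotype`, `beta`, `se`, `t`, `p`
#'   (monomorphic SNPs get NA with `reason`).
#' @export
qtl_scan <- function(dosages, phenotypes, samples = NULL,
                     covariates = c("age", "sex")) {
  stopifnot(is.matrix(dosages), is.matrix(phenotypes))
  subjects <- intersect(colnames(dosages), rownames(phenotypes))
  if (length(subjects) < 3) stop("too few aligned subjects", call. = FALSE)
  g <- dosages[, subjects, drop = FALSE]
  y <- phenotypes[subjects, , drop = FALSE]
  if (!is.null(samples)) {
    samples <- tibble::as_tibble(samples)
    sub_rows <- samples[!duplicated(samples$subject_id), ]
    sub_rows <- sub_rows[match(subjects, sub_rows$subject_id), ]
    covs <- as.data.frame(sub_rows[, intersect(covariates, names(sub_rows)),
                                   drop = FALSE])
    for (v in names(covs)) {
      if (is.character(covs[[v]])) covs[[v]] <- factor(covs[[v]])
    }
    if (ncol(covs) > 0) {
      X <- stats::model.matrix(~ ., data = covs)
      qx <- qr(X)
      for (j in seq_len(ncol(y))) {
        ok <- !is.na(y[, j])
        if (sum(ok) > ncol(X)) {
          y[ok, j] <- stats::resid(stats::lm.fit(X[ok, , drop = FALSE],
                                                 y[ok, j]))
        }
      }
    }
  }
  n <- length(subjects)
  mono <- apply(g, 1, function(v) stats::sd(v, na.rm = TRUE) == 0)
  grid <- tidyr::expand_grid(snp_id = rownames(g),
                             phenotype = colnames(y))
  if (!anyNA(g) && !anyNA(y)) {
    gs <- g - rowMeans(g)
    ys <- sweep(y, 2, colMeans(y))
    g_ss <- rowSums(gs^2)
    y_ss <- colSums(ys^2)
    cross <- gs %*% ys                      # snps x phenotypes
    beta <- sweep(cross, 1, g_ss, "/")
    r <- cross / sqrt(outer(g_ss, y_ss))
    r <- pmin(pmax(r, -1), 1)
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    se <- sqrt(sweep(sweep(pmax(1 - r^2, 0), 2, y_ss, "*"), 1, g_ss, "/") /
                 (n - 2))
    # exact fit: r^2 == 1 gives t = Inf; keep p at the underflow floor
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    res <- tibble::tibble(
      snp_id = rep(rownames(g), times = ncol(y)),
      phenotype = rep(colnames(y), each = nrow(g)),
      beta = as.vector(beta), se = as.vector(se),
      t = as.vector(tval), p = as.vector(p)
    )
  } else {
    res <- purrr::pmap_dfr(grid, function(snp_id, phenotype) {
      a <- g[snp_id, ]
      b <- y[, phenotype]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3 || stats::sd(a[ok]) == 0) {
        return(tibble::tibble(snp_id = snp_id, phenotype = phenotype,
                              beta = NA_real_, se = NA_real_, t = NA_real_,
                              p = NA_real_))
      }
      fit <- stats::lm(b[ok] ~ a[ok])
      cf <- stats::coef(summary(fit))
      tibble::tibble(snp_id = snp_id, phenotype = phenotype,
                     beta = cf[2, 1], se = cf[2, 2], t = cf[2, 3],
                     p = cf[2, 4])
    })
    res <- res[match(paste(grid$snp_id, grid$phenotype),
                     paste(res$snp_id, res$phenotype)), ]
  }
  res$reason <- NA_character_
  is_mono <- res$snp_id %in% rownames(g)[mono]
  res$beta[is_mono] <- NA_real_
  res$se[is_mono] <- NA_real_
  res$t[is_mono] <- NA_real_
  res$p[is_mono] <- NA_real_
  res$reason[is_mono] <- "monomorphic"
  res
}

#' Discover candidate mediation triplets
#'
#' SNPs significantly associated with both the trained-immunity outcome and
#' a DNAm-C phenotype (both p < `alpha`) define (SNP, probe, cytokine)
#' triplets for bidirectional mediation.
#'
#' @param qtl_ti QTL scan of TI phenotypes (from [qtl_scan()]; `phenotype`
#'   holds the cytokine).
#' @param qtl_dnamc QTL scan of DNAm-C phenotypes (`phenotype` holds the
#'   probe id).
#' @param alpha Qualification threshold (default 0.05).
#' @return Tibble: `snp_id`, `probe_id`, `cytokine`, `p_snp_ti`,
#'   `p_snp_dnamc`, sorted deterministically.
#' @export
discover_triplets <- function(qtl_ti, qtl_dnamc, alpha = 0.05) {
  a <- qtl_ti[!is.na(qtl_ti$p) & qtl_ti$p < alpha,
              c("snp_id", "phenotype", "p")]
  b <- qtl_dnamc[!is.na(qtl_dnamc$p) & qtl_dnamc$p < alpha,
                 c("snp_id", "phenotype", "p")]
  names(a) <- c("snp_id", "cytokine", "p_snp_ti")
  names(b) <- c("snp_id", "probe_id", "p_snp_dnamc")
  out <- dplyr::inner_join(a, b, by = "snp_id",
                           relationship = "many-to-many")
  out <- out[, c("snp_id", "probe_id", "cytokine", "p_snp_ti",
                 "p_snp_dnamc")]
  dplyr::arrange(out, .data$snp_id, .data$probe_id, .data$cytokine)
}

#' Causal mediation analysis (one direction)
#'
#' Quasi-Bayesian mediation in the linear, no-interaction setting: the
#' mediator model `m = a0 + a x + covs` and outcome model
#' `y = b0 + c' x + b m + covs` are fitted by OLS; `n_sims` coefficient
#' vectors are drawn from each fit's asymptotic normal; per draw,
#' ACME = a b, ADE = c', total = ACME + ADE. Point estimates are draw
#' means, intervals 2.5/97.5 percentiles, and the p-value is the two-sided
#' simulation p with the add-one convention. Proportion mediated is the
#' median over draws of ACME / (ACME + ADE), flagged unstable when the
#' total effect is within two standard errors of zero.
#'
#' @param x Exposure (SNP dosage) vector.
#' @param m Mediator vector.
#' @param y Outcome vector.
#' @param covariates Optional data frame of covariates for both models.
#' @param n_sims Monte-Carlo draws (default 1000).
#' @param seed RNG seed.
#' @return One-row tibble of class `mediation_fit`: `acme`, `acme_lo`,
#'   `acme_hi`, `acme_p`, `ade`, `ade_p`, `total`, `total_p`,
#'   `prop_mediated`, `prop_unstable`, `n`, `n_sims`. Draws are kept in the
#'   `draws` attribute.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL, n_sims = 1000,
                          seed = 1) {
  d <- data.frame(x = x, m = m, y = y)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 30) {
    stop("need >= 30 complete triplet rows (got ", nrow(d), ")",
         call. = FALSE)
  }
  cov_terms <- setdiff(names(d), c("x", "m", "y"))
  f_med <- stats::as.formula(paste(c("m ~ x", cov_terms), collapse = " + "))
  f_out <- stats::as.formula(paste(c("y ~ x + m", cov_terms),
                                   collapse = " + "))
  fit_m <- stats::lm(f_med, data = d)
  fit_y <- stats::lm(f_out, data = d)
  if (any(is.na(stats::coef(fit_m))) || any(is.na(stats::coef(fit_y)))) {
    stop("singular design in mediation models", call. = FALSE)
  }
  set.seed(seed)
  draw_m <- MASS::mvrnorm(n_sims, stats::coef(fit_m), stats::vcov(fit_m))
  draw_y <- MASS::mvrnorm(n_sims, stats::coef(fit_y), stats::vcov(fit_y))
  a_d <- draw_m[, "x"]
  b_d <- draw_y[, "m"]
  cp_d <- draw_y[, "x"]
  acme_d <- a_d * b_d
  ade_d <- cp_d
  total_d <- acme_d + ade_d
  sim_p <- function(dr) {
    min(1, 2 * (1 + min(sum(dr <= 0), sum(dr >= 0))) / (n_sims + 1))
  }
  total_pt <- mean(total_d)
  unstable <- abs(total_pt) < 2 * stats::sd(total_d)
  out <- tibble::tibble(
    acme = mean(acme_d),
    acme_lo = stats::quantile(acme_d, 0.025, names = FALSE),
    acme_hi = stats::quantile(acme_d, 0.975, names = FALSE),
    acme_p = sim_p(acme_d),
    ade = mean(ade_d),
    ade_p = sim_p(ade_d),
    total = total_pt,
    total_p = sim_p(total_d),
    prop_mediated = stats::median(acme_d / total_d),
    prop_unstable = unstable,
    n = nrow(d),
    n_sims = as.integer(n_sims)
  )
  out <- tibble::new_tibble(out, class = "mediation_fit")
  attr(out, "draws") <- list(acme = acme_d, ade = ade_d, total = total_d)
  out
}

#' Bidirectional mediation with direction triage
#'
#' Runs [fit_mediation()] in both directions for one triplet — D1 treats
#' the methylation change as mediator and the trained-immunity response as
#' outcome, D2 swaps the two — and classifies the result by the two ACME
#' p-values: `unidirectional_D1` (p1 < alpha, p2 >= alpha),
#' `unidirectional_D2`, `bidirectional` (both), or `none`.
#'
#' @param x Exposure (SNP dosage).
#' @param dnamc Methylation-change values (mediator in D1).
#' @param ti Trained-immunity values (outcome in D1).
#' @param covariates Optional data frame (age, sex) used in both models.
#' @param alpha Direction significance threshold (default 0.05).
#' @inheritParams fit_mediation
#' @return Tibble with two rows (`direction` D1/D2) and the mediation
#'   columns; the classification is in the `classification` column and
#'   attribute.
#' @export
bidirectional_mediation <- function(x, dnamc, ti, covariates = NULL,
                                    n_sims = 1000, seed = 1, alpha = 0.05) {
  d1 <- tryCatch(fit_mediation(x, m = dnamc, y = ti,
                               covariates = covariates, n_sims = n_sims,
                               seed = seed),
                 error = function(e) NULL)
  d2 <- tryCatch(fit_mediation(x, m = ti, y = dnamc,
                               covariates = covariates, n_sims = n_sims,
                               seed = seed + 1),
                 error = function(e) NULL)
  if (is.null(d1) || is.null(d2)) {
    cls <- NA_character_
  } else {
    s1 <- d1$acme_p < alpha
    s2 <- d2$acme_p < alpha
    cls <- dplyr::case_when(
      s1 & !s2 ~ "unidirectional_D1",
      !s1 & s2 ~ "unidirectional_D2",
      s1 & s2 ~ "bidirectional",
      TRUE ~ "none"
    )
  }
  empty <- tibble::tibble(acme = NA_real_, acme_lo = NA_real_,
                          acme_hi = NA_real_, acme_p = NA_real_,
                          ade = NA_real_, ade_p = NA_real_,
                          total = NA_real_, total_p = NA_real_,
                          prop_mediated = NA_real_, prop_unstable = NA,
                          n = NA_integer_, n_sims = NA_integer_)
  rows <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(direction = "D1"),
                     if (is.null(d1)) empty else tibble::as_tibble(d1)),
    dplyr::bind_cols(tibble::tibble(direction = "D2"),
                     if (is.null(d2)) empty else tibble::as_tibble(d2))
  )
  rows$classification <- cls
  attr(rows, "classification") <- cls
  rows
}

#' Cis-window extraction and enrichment of cytokine-QTL p-values
#'
#' Extracts the cytokine-QTL p-values of SNPs lying within `window` bp
#' (inclusive) of any listed CpG on the same chromosome, draws a
#' size-matched random SNP set from the remainder, and compares the two
#' p-value sets by a Kolmogorov-Smirnov test.
#'
#' @param cpgs Tibble with `probe_id`, `chromosome`, `position` (1-based).
#' @param snps Tibble with `snp_id`, `chromosome`, `position`.
#' @param qtl QTL scan results for one cytokine (`snp_id`, `p`).
#' @param window Half-width in bp (default 250000).
#' @param seed Seed for the random draw.
#' @return List: `cis` (tibble of cis SNPs with p), `random` (tibble),
#'   `ks` (one-row tibble: `n_cis`, `n_random`, `statistic`, `p`).
#' @export
cis_window_enrichment <- function(cpgs, snps, qtl, window = 250000,
                                  seed = 1) {
  cpgs <- tibble::as_tibble(cpgs)
  snps <- tibble::as_tibble(snps)
  cis_flag <- vapply(seq_len(nrow(snps)), function(i) {
    same <- cpgs$chromosome == snps$chromosome[i]
    any(same & abs(cpgs$position - snps$position[i]) <= window)
  }, logical(1))
  if (!any(cis_flag)) {
    stop("no SNP within ", window, " bp of any CpG", call. = FALSE)
  }
  p_by_snp <- qtl$p[match(snps$snp_id, qtl$snp_id)]
  cis <- tibble::tibble(snp_id = snps$snp_id[cis_flag],
                        p = p_by_snp[cis_flag])
  pool <- which(!cis_flag & !is.na(p_by_snp))
  set.seed(seed)
  pick <- sample(pool, min(length(pool), nrow(cis)))
  random <- tibble::tibble(snp_id = snps$snp_id[pick], p = p_by_snp[pick])
  ks <- suppressWarnings(stats::ks.test(cis$p, random$p))
  list(cis = cis, random = random,
       ks = tibble::tibble(n_cis = nrow(cis), n_random = nrow(random),
                           statistic = unname(ks$statistic),
                           p = ks$p.value))
}
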