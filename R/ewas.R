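#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values; NAs are excluded from the adjustment and re-inserted
#' in place. Input p-values outside `[0, 1]` are an error.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Vector of q-values, capped at 1, monotone in p-rank.
#' @export
bh_fdr <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-value outside [0, 1]: ", format(p[bad][1]), call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; 1 under the null.
#'
#' @param p Vector of p-values (>= 100 recommended; fewer is an error).
#' @return Scalar lambda.
#' @export
compute_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) stop("need >= 100 p-values", call. = FALSE)
  if (length(unique(p)) == 1) {
    warning("degenerate p-value distribution (all equal)", call. = FALSE)
  }
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' Annual-phase seasonality covariates
#'
#' Harmonic encoding of the collection date:
#' `sin(2 pi doy / 365.25)` and `cos(2 pi doy / 365.25)` with `doy` the day
#' of year. Missing dates propagate as NA.
#'
#' @param dates Date vector.
#' @return Tibble with columns `season_sin`, `season_cos`.
#' @export
seasonality_terms <- function(dates) {
  doy <- as.numeric(format(as.Date(dates), "%j"))
  phase <- 2 * pi * doy / 365.25
  tibble::tibble(season_sin = sin(phase), season_cos = cos(phase))
}

# Build the per-sample covariate model frame shared by the EWAS fitters.
# Cell fractions sum to 1, so the first (reference) cell type is dropped to
# keep the design full rank alongside the intercept.
build_covariate_frame <- function(samples, covariates, cell_fractions) {
  df <- tibble::as_tibble(samples)
  miss <- setdiff(covariates, names(df))
  if (length(miss) > 0) {
    stop("covariate(s) not in sample sheet: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- df[, c("sample_id", "subject_id", "timepoint", covariates),
            drop = FALSE]
  for (v in covariates) {
    if (is.character(out[[v]]) || is.logical(out[[v]])) {
      out[[v]] <- factor(out[[v]])
    }
  }
  if (!is.null(cell_fractions)) {
    cf <- tibble::as_tibble(cell_fractions)
    stopifnot("sample_id" %in% names(cf))
    types <- setdiff(names(cf), "sample_id")
    cf <- cf[, c("sample_id", types[-1]), drop = FALSE]  # drop reference type
    out <- dplyr::left_join(out, cf, by = "sample_id")
  }
  out
}

ewas_result_tibble <- function(df, model_tag) {
  df$q <- bh_fdr(df$p)
  out <- tibble::new_tibble(df, class = "ewas_result")
  attr(out, "model_tag") <- model_tag
  out
}

#' Longitudinal mixed-model EWAS
#'
#' Fits, per probe, a linear mixed model of the M value on timepoint
#' (unordered factor, T0 reference) with a random subject intercept (REML)
#' and the supplied covariates. The `"overall"` contrast reports a joint
#' 2-df test of the T14 and T90 terms (Satterthwaite F); pairwise contrasts
#' restrict to the two timepoints and report that single coefficient.
#' Probes whose random-effect variance collapses to the boundary are
#' refitted by OLS with cluster-robust (subject) standard errors and flagged
#' `model = "ols_cluster"`.
#'
#' @param mvals Probes x samples matrix of M values (NA allowed; complete
#'   cases per probe).
#' @param samples Sample sheet (see [read_sample_sheet()]).
#' @param contrast One of `"overall"`, `"T14-T0"`, `"T90-T0"`, `"T90-T14"`.
#' @param covariates Sample-sheet columns used as fixed covariates
#'   (default `c("age", "sex", "plate")`).
#' @param cell_fractions Optional tibble (`sample_id` + one column per cell
#'   type); the first type is dropped as the reference composition.
#' @param extra_covariates Optional per-sample tibble of additional numeric
#'   covariates (rows aligned with `samples`), e.g. [seasonality_terms()].
#' @param probes Optional probe subset.
#' @return `ewas_result` tibble: `probe_id`, `estimate`, `se`, `stat`, `p`,
#'   `q`, `n_used`, `model`. For `"overall"` the estimate/se are the T90-T0
#'   coefficient and `stat` is the joint F.
#' @export
fit_mixed_ewas <- function(mvals, samples,
                           contrast = c("overall", "T14-T0", "T90-T0",
                                        "T90-T14"),
                           covariates = c("age", "sex", "plate"),
                           cell_fractions = NULL,
                           extra_covariates = NULL,
                           probes = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(is.matrix(mvals))
  frame <- build_covariate_frame(samples, covariates, cell_fractions)
  if (!is.null(extra_covariates)) {
    frame <- dplyr::bind_cols(frame, tibble::as_tibble(extra_covariates))
  }
  stopifnot(all(frame$sample_id %in% colnames(mvals)))

  tps <- if (contrast == "overall") {
    c("T0", "T14", "T90")
  } else {
    rev(strsplit(contrast, "-")[[1]])  # reference first
  }
  frame <- frame[frame$timepoint %in% tps, , drop = FALSE]
  frame$timepoint <- factor(frame$timepoint, levels = tps)
  if (length(unique(frame$timepoint)) < 2) {
    stop("contrast needs >= 2 timepoints present", call. = FALSE)
  }
  n_subj_multi <- sum(table(frame$subject_id) >= 2)
  if (n_subj_multi < 10) {
    stop("need >= 10 subjects with repeated measures", call. = FALSE)
  }
  y_mat <- mvals[, frame$sample_id, drop = FALSE]
  cov_terms <- setdiff(names(frame),
                       c("sample_id", "subject_id", "timepoint"))
  rhs <- paste(c("timepoint", cov_terms, "(1 | subject_id)"), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  probe_set <- if (is.null(probes)) rownames(mvals) else probes

  rows <- lapply(probe_set, function(pb) {
    d <- frame
    d$y <- y_mat[pb, ]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    n_used <- nrow(d)
    fail <- function(reason) {
      tibble::tibble(probe_id = pb, estimate = NA_real_, se = NA_real_,
                     stat = NA_real_, p = NA_real_, n_used = n_used,
                     model = reason)
    }
    if (n_used < 10 || length(unique(d$timepoint)) < 2) {
      return(fail("insufficient_data"))
    }
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) {
      cf <- stats::coef(summary(fit))
      tp_rows <- grep("^timepoint", rownames(cf))
      if (contrast == "overall") {
        L <- matrix(0, length(tp_rows), nrow(cf))
        for (i in seq_along(tp_rows)) L[i, tp_rows[i]] <- 1
        ct <- tryCatch(lmerTest::contest(fit, L, joint = TRUE),
                       error = function(e) NULL)
        if (is.null(ct)) return(fail("contrast_failed"))
        i90 <- tp_rows[length(tp_rows)]
        tibble::tibble(probe_id = pb, estimate = cf[i90, "Estimate"],
                       se = cf[i90, "Std. Error"],
                       stat = ct[["F value"]], p = ct[["Pr(>F)"]],
                       n_used = n_used, model = "lmm")
      } else {
        i <- tp_rows[1]
        tibble::tibble(probe_id = pb, estimate = cf[i, "Estimate"],
                       se = cf[i, "Std. Error"], stat = cf[i, "t value"],
                       p = cf[i, "Pr(>|t|)"], n_used = n_used, model = "lmm")
      }
    } else {
      # boundary/singular random effect: OLS with cluster-robust SE
      ols_form <- stats::as.formula(
        paste("y ~", paste(c("timepoint", cov_terms), collapse = " + ")))
      ols <- tryCatch(stats::lm(ols_form, data = d), error = function(e) NULL)
      if (is.null(ols) || any(is.na(stats::coef(ols)))) {
        return(fail("rank_deficient"))
      }
      V <- sandwich::vcovCL(ols, cluster = d$subject_id)
      b <- stats::coef(ols)
      tp_ix <- grep("^timepoint", names(b))
      df_cl <- length(unique(d$subject_id)) - 1
      if (contrast == "overall") {
        bv <- b[tp_ix]
        W <- drop(t(bv) %*% solve(V[tp_ix, tp_ix]) %*% bv) / length(tp_ix)
        i90 <- tp_ix[length(tp_ix)]
        tibble::tibble(probe_id = pb, estimate = b[i90],
                       se = sqrt(V[i90, i90]), stat = W,
                       p = stats::pf(W, length(tp_ix), df_cl,
                                     lower.tail = FALSE),
                       n_used = n_used, model = "ols_cluster")
      } else {
        i <- tp_ix[1]
        tt <- b[i] / sqrt(V[i, i])
        tibble::tibble(probe_id = pb, estimate = b[i], se = sqrt(V[i, i]),
                       stat = tt,
                       p = 2 * stats::pt(-abs(tt), df_cl),
                       n_used = n_used, model = "ols_cluster")
      }
    }
  })
  ewas_result_tibble(dplyr::bind_rows(rows),
                     model_tag = paste0("mixed_", contrast))
}

# Shared Huber robust-regression engine: outcome ~ predictor + covariates.
# Returns one row per predictor column of x_mat.
robust_scan <- function(x_mat, outcome, covar_df, feature_ids, model_tag,
                        maxit = 50, acc = 1e-8) {
  rows <- lapply(seq_len(nrow(x_mat)), function(i) {
    d <- covar_df
    d$x <- x_mat[i, ]
    d$y <- outcome
    d <- d[stats::complete.cases(d), , drop = FALSE]
    n_used <- nrow(d)
    fail <- function(reason) {
      tibble::tibble(probe_id = feature_ids[i], estimate = NA_real_,
                     se = NA_real_, stat = NA_real_, p = NA_real_,
                     n_used = n_used, model = reason)
    }
    if (n_used < 10) return(fail("insufficient_data"))
    if (stats::sd(d$x) == 0) return(fail("constant predictor"))
    rhs <- paste(c("x", setdiff(names(d), c("x", "y"))), collapse = " + ")
    fit <- tryCatch(
      MASS::rlm(stats::as.formula(paste("y ~", rhs)), data = d,
                psi = MASS::psi.huber, k = 1.345, maxit = maxit, acc = acc),
      error = function(e) NULL)
    if (is.null(fit)) return(fail("fit_failed"))
    tag <- "huber"
    if (!fit$converged) {
      warning("IRLS did not converge for ", feature_ids[i],
              "; last iterate reported", call. = FALSE)
      tag <- "huber_nonconverged"
    }
    cf <- stats::coef(summary(fit))
    est <- cf["x", "Value"]
    se <- cf["x", "Std. Error"]
    tt <- est / se
    df_res <- n_used - nrow(cf)
    tibble::tibble(probe_id = feature_ids[i], estimate = est, se = se,
                   stat = tt, p = 2 * stats::pt(-abs(tt), df_res),
                   n_used = n_used, model = tag)
  })
  ewas_result_tibble(dplyr::bind_rows(rows), model_tag = model_tag)
}

#' Robust-regression EWAS of trained immunity on methylation
#'
#' Per probe, a Huber M-estimated linear regression (tuning constant 1.345,
#' IRLS to `1e-8` or 50 iterations) of the normalized trained-immunity
#' response on the probe's M value at one timepoint, adjusting for the
#' supplied covariates. Standard errors are the asymptotic M-estimator
#' (sandwich-form) errors reported by the IRLS fit; p-values use a t
#' reference with residual degrees of freedom.
#'
#' @param mvals Probes x samples M matrix restricted to one timepoint.
#' @param ti Tibble from [compute_ti()] filtered to one cytokine (columns
#'   `subject_id`, `ti_norm`).
#' @param samples Sample sheet rows matching `colnames(mvals)`.
#' @inheritParams fit_mixed_ewas
#' @return `ewas_result` tibble (estimate = methylation coefficient).
#' @export
fit_robust_ewas <- function(mvals, ti, samples,
                            covariates = c("age", "sex", "plate"),
                            cell_fractions = NULL, probes = NULL) {
  stopifnot(is.matrix(mvals))
  frame <- build_covariate_frame(samples, covariates, cell_fractions)
  frame <- frame[match(colnames(mvals), frame$sample_id), , drop = FALSE]
  ti <- tibble::as_tibble(ti)
  stopifnot(all(c("subject_id", "ti_norm") %in% names(ti)))
  outcome <- ti$ti_norm[match(frame$subject_id, ti$subject_id)]
  covar_df <- frame[, setdiff(names(frame),
                              c("sample_id", "subject_id", "timepoint")),
                    drop = FALSE]
  probe_set <- if (is.null(probes)) rownames(mvals) else probes
  robust_scan(mvals[probe_set, , drop = FALSE], outcome,
              as.data.frame(covar_df), probe_set, model_tag = "robust_ti")
}

#' Residualize methylation on per-timepoint technical covariates
#'
#' Per probe and per timepoint, replaces M values by the residuals of an
#' OLS regression on that timepoint's covariates (by default plate batch
#' and cell fractions), so that between-timepoint differences of the
#' residuals ("DNAm-C") are free of composition and batch differences.
#'
#' @param mvals Probes x samples M matrix (all timepoints).
#' @param samples Sample sheet.
#' @param cell_fractions Tibble of per-sample fractions (first type dropped).
#' @param covariates Sample-sheet columns to residualize on (default
#'   `"plate"`).
#' @return Matrix of residuals, same dimensions/order as `mvals`.
#' @export
residualize_by_timepoint <- function(mvals, samples, cell_fractions = NULL,
                                     covariates = "plate") {
  stopifnot(is.matrix(mvals))
  frame <- build_covariate_frame(samples, covariates, cell_fractions)
  frame <- frame[match(colnames(mvals), frame$sample_id), , drop = FALSE]
  out <- mvals
  for (tp in unique(frame$timepoint)) {
    ix <- which(frame$timepoint == tp)
    covs <- frame[ix, setdiff(names(frame),
                              c("sample_id", "subject_id", "timepoint")),
                  drop = FALSE]
    X <- if (ncol(covs) == 0) {
      matrix(1, length(ix), 1)            # centre only
    } else {
      stats::model.matrix(~ ., data = as.data.frame(covs))
    }
    if (nrow(X) <= ncol(X)) {
      stop("timepoint ", tp, ": fewer samples (", nrow(X),
           ") than covariate parameters (", ncol(X), ")", call. = FALSE)
    }
    qx <- qr(X)
    Y <- mvals[, ix, drop = FALSE]
    complete <- !apply(Y, 1, anyNA)
    if (any(complete)) {
      out[complete, ix] <- t(qr.resid(qx, t(Y[complete, , drop = FALSE])))
    }
    for (i in which(!complete)) {
      y <- Y[i, ]
      ok <- !is.na(y)
      if (sum(ok) <= ncol(X)) next
      out[i, ix[ok]] <- stats::resid(stats::lm.fit(X[ok, , drop = FALSE],
                                                   y[ok]))
    }
  }
  out
}

#' Associate methylation change (DNAm-C) with trained immunity
#'
#' Computes per-subject differences of residualized M values between two
#' timepoints and regresses the trained-immunity response on them (Huber
#' robust regression) with age and sex as covariates.
#'
#' @param resid_mvals Residual matrix from [residualize_by_timepoint()].
#' @param pair One of `"T14-T0"`, `"T90-T0"`, `"T90-T14"`.
#' @param ti Tibble from [compute_ti()] for one cytokine.
#' @param samples Sample sheet.
#' @param covariates Subject-level covariates (default `c("age", "sex")`).
#' @param probes Optional probe subset.
#' @return `ewas_result` tibble.
#' @export
dnamc_association <- function(resid_mvals, pair = c("T90-T0", "T14-T0",
                                                    "T90-T14"),
                              ti, samples, covariates = c("age", "sex"),
                              probes = NULL) {
  pair <- match.arg(pair)
  tps <- strsplit(pair, "-")[[1]]  # later timepoint first
  samples <- tibble::as_tibble(samples)
  sa <- samples[samples$timepoint == tps[2], ]
  sb <- samples[samples$timepoint == tps[1], ]
  shared <- intersect(sa$subject_id, sb$subject_id)
  if (length(shared) < 10) {
    stop("need >= 10 subjects with both timepoints", call. = FALSE)
  }
  cola <- sa$sample_id[match(shared, sa$subject_id)]
  colb <- sb$sample_id[match(shared, sb$subject_id)]
  dn <- resid_mvals[, colb, drop = FALSE] - resid_mvals[, cola, drop = FALSE]
  colnames(dn) <- shared
  if (all(abs(dn) < 1e-12, na.rm = TRUE)) {
    stop("constant predictor: residuals identical at both timepoints",
         call. = FALSE)
  }
  subj <- samples[samples$timepoint == tps[2], ]
  subj <- subj[match(shared, subj$subject_id), ]
  covar_df <- as.data.frame(subj[, covariates, drop = FALSE])
  for (v in names(covar_df)) {
    if (is.character(covar_df[[v]])) covar_df[[v]] <- factor(covar_df[[v]])
  }
  ti <- tibble::as_tibble(ti)
  outcome <- ti$ti_norm[match(shared, ti$subject_id)]
  probe_set <- if (is.null(probes)) rownames(dn) else probes
  robust_scan(dn[probe_set, , drop = FALSE], outcome, covar_df, probe_set,
              model_tag = paste0("dnamc_", pair))
}

#' Sensitivity refit of an EWAS with a design variant
#'
#' Re-runs [fit_mixed_ewas()] under one of three variants and summarises
#' concordance with the base result on a probe set of interest: the
#' 12-cell-type deconvolution panel instead of the 6-type panel, added
#' seasonality covariates, or the age-over-30 subgroup.
#'
#' @param mvals,samples,contrast,covariates,cell_fractions As in
#'   [fit_mixed_ewas()].
#' @param base `ewas_result` from the base fit.
#' @param variant `"cells12"`, `"seasonality"` or `"age_over_30"`.
#' @param cell_fractions_12 12-type fractions tibble (variant `"cells12"`).
#' @param probes Probes to refit; default: base probes with `p < p_select`.
#' @param p_select Selection threshold for the default probe set (default
#'   `1e-5`, the suggestive threshold).
#' @return List with `results` (`ewas_result`) and `concordance` (one-row
#'   tibble: `n_probes`, `frac_same_direction`, `frac_retained_suggestive`).
#' @export
sensitivity_refit <- function(mvals, samples, base,
                              variant = c("cells12", "seasonality",
                                          "age_over_30"),
                              contrast = "overall",
                              covariates = c("age", "sex", "plate"),
                              cell_fractions = NULL,
                              cell_fractions_12 = NULL,
                              probes = NULL, p_select = 1e-5) {
  variant <- match.arg(variant)
  if (is.null(probes)) {
    probes <- base$probe_id[!is.na(base$p) & base$p < p_select]
  }
  if (length(probes) == 0) stop("no probes selected for refit", call. = FALSE)
  samples <- tibble::as_tibble(samples)
  extra <- NULL
  cf <- cell_fractions
  if (variant == "cells12") {
    if (is.null(cell_fractions_12)) {
      stop("variant 'cells12' needs cell_fractions_12", call. = FALSE)
    }
    cf <- cell_fractions_12
  } else if (variant == "seasonality") {
    if (!"collection_date" %in% names(samples)) {
      stop("variant 'seasonality' needs collection_date", call. = FALSE)
    }
    extra <- seasonality_terms(samples$collection_date)
  } else if (variant == "age_over_30") {
    keep <- samples$age > 30
    if (!any(keep)) stop("empty age>30 subset", call. = FALSE)
    samples <- samples[keep, , drop = FALSE]
    mvals <- mvals[, samples$sample_id, drop = FALSE]
    if (!is.null(cf)) cf <- cf[cf$sample_id %in% samples$sample_id, ]
  }
  res <- fit_mixed_ewas(mvals, samples, contrast = contrast,
                        covariates = covariates, cell_fractions = cf,
                        extra_covariates = extra, probes = probes)
  b <- base[match(probes, base$probe_id), ]
  v <- res[match(probes, res$probe_id), ]
  ok <- !is.na(b$estimate) & !is.na(v$estimate)
  concordance <- tibble::tibble(
    variant = variant,
    n_probes = length(probes),
    frac_same_direction = mean(sign(b$estimate[ok]) == sign(v$estimate[ok])),
    frac_retained_suggestive = mean(!is.na(v$p) & v$p < p_select)
  )
  list(results = res, concordance = concordance)
}
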