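#' Convert methylation beta values to M values
#'
#' The modelling scale for array methylation is the base-2 logit of the
#' methylation fraction: `M = log2(beta / (1 - beta))`. Beta values of
#' exactly 0 or 1 are clamped to `eps` / `1 - eps` with a warning so the
#' transform stays finite.
#'
#' @param beta Numeric vector or matrix of beta values in `[0, 1]` (NA
#'   allowed).
#' @param eps Clamp applied to exact 0/1 before the logit (default `1e-6`).
#' @return Object of the same shape on the M scale.
#' @examples
#' beta_to_m(0.8) # log2(4) = 2
#' m_to_beta(beta_to_m(0.33))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  x <- as.numeric(beta)
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop("beta values outside [0, 1]: e.g. ", format(x[bad][1]), call. = FALSE)
  }
  at_edge <- !is.na(x) & (x == 0 | x == 1)
  if (any(at_edge)) {
    warning(sum(at_edge), " beta value(s) at exactly 0/1 clamped to eps = ",
            eps, call. = FALSE)
    x[!is.na(x) & x == 0] <- eps
    x[!is.na(x) & x == 1] <- 1 - eps
  }
  out <- log2(x / (1 - x))
  if (is.matrix(beta)) {
    out <- matrix(out, nrow = nrow(beta), dimnames = dimnames(beta))
  }
  out
}

#' @rdname beta_to_m
#' @param m Numeric vector or matrix of M values.
#' @export
m_to_beta <- function(m) {
  out <- 2^m / (1 + 2^m)
  # large positive M overflows 2^m; logistic limit is 1
  out[!is.na(m) & is.infinite(2^m)] <- 1
  if (is.matrix(m)) {
    out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  }
  out
}

#' Mask extreme outliers by the Tukey 3-IQR rule
#'
#' Values strictly below `Q1 - 3 IQR` or strictly above `Q3 + 3 IQR` are set
#' to `NA`. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7). The operation is idempotent: fences are
#' computed on the non-missing values, and masked values are extreme by
#' construction, so re-masking changes nothing.
#'
#' @param x Numeric vector (one probe across samples), NA allowed.
#' @param k Fence multiplier (default 3, the extreme-outlier rule).
#' @return List with `values` (masked vector) and `mask` (logical, TRUE
#'   where newly masked).
#' @export
tukey_mask <- function(x, k = 3) {
  if (sum(!is.na(x)) == 0) stop("all values missing", call. = FALSE)
  if (sum(!is.na(x)) < 4) {
    stop("need >= 4 non-missing values to place Tukey fences", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  mask <- !is.na(x) & (x < q[1] - k * iqr | x > q[2] + k * iqr)
  x[mask] <- NA
  list(values = x, mask = mask)
}

#' Apply Tukey masking to every probe of a methylation matrix
#'
#' @param mat Probes x samples numeric matrix.
#' @inheritParams tukey_mask
#' @return Matrix with per-probe outliers set to NA. Probes with fewer than
#'   4 non-missing values are left untouched.
#' @export
mask_outliers <- function(mat, k = 3) {
  stopifnot(is.matrix(mat))
  out <- t(apply(mat, 1, function(v) {
    if (sum(!is.na(v)) < 4) return(v)
    tukey_mask(v, k = k)$values
  }))
  dimnames(out) <- dimnames(mat)
  out
}

#' Inverse-rank normal transformation (Blom offset)
#'
#' Maps values to normal quantiles `qnorm((r - 3/8) / (n + 1/4))` where `r`
#' is the average rank (ties share a rank, hence equal outputs) and `n` the
#' number of non-missing values. Missing values propagate.
#'
#' @param x Numeric vector with at least 3 non-missing values.
#' @param offset Rank offset; 3/8 (Blom) by default.
#' @return Numeric vector of the same length.
#' @export
inverse_rank_normalize <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 non-missing values", call. = FALSE)
  if (length(unique(x[ok])) == 1) {
    stop("all values identical; ranks undefined", call. = FALSE)
  }
  r <- rank(x[ok], ties.method = "average")
  z <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  out
}

#' Reference-based cell-type deconvolution
#'
#' Estimates leukocyte composition per sample by simplex-constrained least
#' squares against a panel of cell-type reference methylation profiles
#' (mean beta per marker probe and cell type): minimise `||x - R f||^2`
#' subject to `f >= 0`, `sum(f) = 1`. The sum-to-one constraint is enforced
#' by augmenting the system with a heavily weighted row of ones and the
#' non-negativity by NNLS.
#'
#' @param betas Probes x samples beta matrix containing (at least) the
#'   reference marker probes as rows.
#' @param reference Marker-probes x cell-types matrix of mean beta values;
#'   rownames are probe ids, colnames cell-type labels.
#' @param lambda Weight of the sum-to-one augmentation row (default 1000).
#' @return Tibble with `sample_id` and one fraction column per cell type;
#'   rows sum to 1.
#' @export
deconvolve_cells <- function(betas, reference, lambda = 1000) {
  stopifnot(is.matrix(betas), is.matrix(reference))
  missing_probes <- setdiff(rownames(reference), rownames(betas))
  if (length(missing_probes) > 0) {
    stop("reference probes absent from matrix: ",
         paste(utils::head(missing_probes, 3), collapse = ", "), call. = FALSE)
  }
  if (nrow(reference) < ncol(reference)) {
    stop("need at least as many marker probes as cell types", call. = FALSE)
  }
  if (qr(reference)$rank < ncol(reference)) {
    stop("reference profile matrix is rank-deficient", call. = FALSE)
  }
  x <- betas[rownames(reference), , drop = FALSE]
  r_aug <- rbind(reference, lambda * rep(1, ncol(reference)))
  frac <- apply(x, 2, function(v) {
    ok <- !is.na(v)
    f <- pracma::lsqnonneg(r_aug[c(ok, TRUE), , drop = FALSE],
                           c(v[ok], lambda))$x
    s <- sum(f)
    if (s <= 0) stop("degenerate deconvolution fit (all-zero fractions)",
                     call. = FALSE)
    f / s
  })
  out <- tibble::as_tibble(t(frac), .name_repair = "minimal")
  names(out) <- colnames(reference)
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(x)), out)
}

#' Compute trained-immunity responses from paired cytokine measurements
#'
#' The trained-immunity (TI) outcome for a cytokine is the log10 fold change
#' of stimulated production at day 90 versus baseline,
#' `ti_raw = log10(c_T90 / c_T0)`, corrected for measurement batch by
#' residualising on the batch factor (grand mean retained), then mapped
#' through the inverse-rank normal transform.
#'
#' @param cytokines Tibble/data frame with columns `subject_id`, `cytokine`,
#'   `conc_T0`, `conc_T90` (positive concentrations) and optionally `batch`.
#' @param batch Optional column name holding the batch label (default
#'   `"batch"` if present, otherwise a single batch is assumed).
#' @return Tibble with `subject_id`, `cytokine`, `ti_raw`, `ti_corrected`,
#'   `ti_norm` (one row per subject x cytokine). Subjects with a missing
#'   member of the pair are dropped with a message.
#' @export
compute_ti <- function(cytokines, batch = "batch") {
  df <- tibble::as_tibble(cytokines)
  req <- c("subject_id", "cytokine", "conc_T0", "conc_T90")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("cytokine table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  incomplete <- is.na(df$conc_T0) | is.na(df$conc_T90)
  if (any(incomplete)) {
    message("dropping ", sum(incomplete),
            " subject/cytokine pair(s) with a missing measurement")
    df <- df[!incomplete, , drop = FALSE]
  }
  nonpos <- df$conc_T0 <= 0 | df$conc_T90 <= 0
  if (any(nonpos)) {
    stop("nonpositive cytokine concentration for subject(s): ",
         paste(utils::head(unique(df$subject_id[nonpos]), 5), collapse = ", "),
         call. = FALSE)
  }
  has_batch <- batch %in% names(df) && length(unique(df[[batch]])) > 1
  df$ti_raw <- log10(df$conc_T90 / df$conc_T0)
  out <- df |>
    dplyr::group_by(.data$cytokine) |>
    dplyr::group_modify(function(d, key) {
      if (has_batch) {
        fit <- stats::lm(d$ti_raw ~ factor(d[[batch]]))
        d$ti_corrected <- mean(d$ti_raw) + stats::resid(fit)
      } else {
        d$ti_corrected <- d$ti_raw
      }
      d$ti_norm <- inverse_rank_normalize(d$ti_corrected)
      d
    }) |>
    dplyr::ungroup()
  dplyr::select(out, "subject_id", "cytokine", "ti_raw", "ti_corrected",
                "ti_norm")
}

#' Scan principal components of methylation against sample covariates
#'
#' Computes the top `k` sample-space principal components of the centred
#' M-value matrix (rows with missing values are mean-imputed for the
#' decomposition only) and regresses each PC on each covariate with a
#' univariable linear model. Mirrors the standard EWAS QC heatmap of
#' PC-covariate associations.
#'
#' @param mvals Probes x samples matrix of M values.
#' @param covariates Data frame of per-sample covariates, rows aligned with
#'   the matrix columns (a `sample_id` column, if present, is matched
#'   against `colnames(mvals)`).
#' @param k Number of PCs (default 30, capped at the matrix rank).
#' @return Object of class `pc_scan`: a tibble with `pc`, `covariate`, `p`,
#'   plus attributes `var_explained` (per-PC fraction) and `cum_var`
#'   (cumulative fraction at `k`).
#' @export
pca_covariate_scan <- function(mvals, covariates, k = 30) {
  stopifnot(is.matrix(mvals))
  covariates <- tibble::as_tibble(covariates)
  if ("sample_id" %in% names(covariates)) {
    stopifnot(all(colnames(mvals) %in% covariates$sample_id))
    covariates <- covariates[match(colnames(mvals), covariates$sample_id), ]
    covariates$sample_id <- NULL
  } else {
    stopifnot(nrow(covariates) == ncol(mvals))
  }
  x <- mvals
  na_rows <- which(rowSums(is.na(x)) > 0)
  for (i in na_rows) {
    v <- x[i, ]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    x[i, ] <- v
  }
  x <- x - rowMeans(x)
  k <- min(k, ncol(x) - 1, nrow(x))
  sv <- svd(x, nu = 0, nv = k)
  d2 <- sv$d^2
  pcs <- sv$v %*% diag(sv$d[seq_len(k)], k, k)
  colnames(pcs) <- paste0("PC", seq_len(k))
  var_explained <- d2[seq_len(k)] / sum(d2)

  grid <- tidyr::expand_grid(pc = seq_len(k), covariate = names(covariates))
  grid$p <- purrr::pmap_dbl(grid, function(pc, covariate) {
    z <- covariates[[covariate]]
    if (length(unique(z[!is.na(z)])) < 2) {
      warning("constant covariate '", covariate, "': p set to NA",
              call. = FALSE)
      return(NA_real_)
    }
    if (is.character(z) || is.logical(z)) z <- factor(z)
    fit <- stats::lm(pcs[, pc] ~ z)
    f <- summary(fit)$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  })
  structure(grid,
            class = c("pc_scan", class(grid)),
            var_explained = var_explained,
            cum_var = sum(var_explained))
}
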