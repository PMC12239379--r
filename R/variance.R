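#' Select layer features associated with trained immunity
#'
#' Candidate predictors are features whose Spearman correlation with the
#' trained-immunity outcome has p < `alpha`. For the methylation layer the
#' candidate list is instead supplied externally (the EWAS-significant CpG
#' set), bypassing the marginal screen.
#'
#' @param layer Subjects x features numeric matrix.
#' @param ti Numeric vector of normalized TI values aligned with the rows.
#' @param alpha Screening threshold (default 0.05).
#' @param preselected Optional character vector of feature names to use
#'   as-is (e.g. EWAS-significant CpGs).
#' @return Tibble: `feature`, `rho`, `p`, `selected`, `reason`.
#' @export
select_layer_features <- function(layer, ti, alpha = 0.05,
                                  preselected = NULL) {
  if (is.null(layer) || ncol(layer) == 0) {
    warning("empty layer: no candidates", call. = FALSE)
    return(tibble::tibble(feature = character(0), rho = numeric(0),
                          p = numeric(0), selected = logical(0),
                          reason = character(0)))
  }
  stopifnot(nrow(layer) == length(ti))
  res <- purrr::map_dfr(colnames(layer), function(f) {
    v <- layer[, f]
    ok <- !is.na(v) & !is.na(ti)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0) {
      return(tibble::tibble(feature = f, rho = NA_real_, p = NA_real_,
                            selected = FALSE, reason = "constant_or_missing"))
    }
    ct <- suppressWarnings(stats::cor.test(v[ok], ti[ok],
                                           method = "spearman"))
    tibble::tibble(feature = f, rho = unname(ct$estimate), p = ct$p.value,
                   selected = ct$p.value < alpha, reason = NA_character_)
  })
  if (!is.null(preselected)) {
    res$selected <- res$feature %in% preselected
    res$reason[!res$selected] <- "not_in_preselected_list"
  }
  res
}

#' Prune collinear candidate predictors
#'
#' Greedy within-layer collinearity pruning: among pairs of candidates with
#' absolute Spearman correlation above `threshold`, the member with the
#' weaker TI association (larger Spearman p) is dropped; pairs are visited
#' in descending |rho| (ties broken by feature id) and the rule repeats
#' until no pair exceeds the threshold.
#'
#' @param layer Subjects x features matrix containing the candidates.
#' @param candidates Character vector of candidate feature names.
#' @param ti Normalized TI vector aligned with rows.
#' @param threshold Correlation threshold (default 0.4, applied to |rho|).
#' @return Character vector of retained features (order of `candidates`).
#' @export
prune_collinear <- function(layer, candidates, ti, threshold = 0.4) {
  if (length(candidates) <= 1) return(candidates)
  x <- layer[, candidates, drop = FALSE]
  ti_p <- vapply(candidates, function(f) {
    ok <- !is.na(x[, f]) & !is.na(ti)
    suppressWarnings(stats::cor.test(x[ok, f], ti[ok],
                                     method = "spearman")$p.value)
  }, numeric(1))
  keep <- candidates
  repeat {
    if (length(keep) <= 1) break
    rho <- suppressWarnings(
      stats::cor(x[, keep, drop = FALSE], method = "spearman",
                 use = "pairwise.complete.obs"))
    diag(rho) <- 0
    pairs <- which(abs(rho) > threshold, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs) == 0) break
    ord <- order(-abs(rho[pairs]), keep[pairs[, 1]], keep[pairs[, 2]])
    top <- pairs[ord[1], ]
    f1 <- keep[top[1]]
    f2 <- keep[top[2]]
    drop_f <- if (ti_p[f1] > ti_p[f2]) f1 else f2
    keep <- setdiff(keep, drop_f)
  }
  candidates[candidates %in% keep]
}

#' Adjusted R-squared of TI on selected predictors
#'
#' OLS of the normalized TI outcome on the selected features;
#' `adj R2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param features Subjects x features matrix (the selected predictors).
#' @param ti Normalized TI vector.
#' @return One-row tibble: `n`, `p_features`, `r_squared`, `adj_r_squared`.
#' @export
fit_variance_model <- function(features, ti) {
  if (is.null(features) || ncol(features) == 0) {
    return(tibble::tibble(n = sum(!is.na(ti)), p_features = 0L,
                          r_squared = 0, adj_r_squared = 0))
  }
  ok <- stats::complete.cases(features) & !is.na(ti)
  x <- features[ok, , drop = FALSE]
  y <- ti[ok]
  n <- length(y)
  p <- ncol(x)
  if (p >= n - 1) {
    stop("too many predictors (", p, ") for n = ", n,
         "; prune more aggressively", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(n = n, p_features = as.integer(p),
                 r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared)
}

#' Variance explained per layer and combined
#'
#' Runs the full select / prune / fit procedure per layer, then fits the
#' combined model on the concatenation of each layer's pruned predictor set
#' (cross-layer collinearity is not re-pruned).
#'
#' @param layers Named list of subjects x features matrices.
#' @param ti Normalized TI vector aligned with rows of every layer.
#' @param preselected Named list: layer name -> preselected feature set
#'   (e.g. `list(methylation = ewas_cpgs)`).
#' @param alpha,threshold Screening and pruning parameters.
#' @return List of class `variance_report`: `per_layer` tibble (layer,
#'   n_candidates, n_selected, r_squared, adj_r_squared), `combined`
#'   one-row tibble, `selected` named list of retained features.
#' @export
variance_explained <- function(layers, ti, preselected = list(),
                               alpha = 0.05, threshold = 0.4) {
  stopifnot(is.list(layers), !is.null(names(layers)))
  selected <- list()
  per_layer <- purrr::map_dfr(names(layers), function(nm) {
    layer <- layers[[nm]]
    sel <- select_layer_features(layer, ti, alpha = alpha,
                                 preselected = preselected[[nm]])
    cand <- sel$feature[sel$selected]
    pruned <- prune_collinear(layer, cand, ti, threshold = threshold)
    selected[[nm]] <<- pruned
    fitrow <- fit_variance_model(layer[, pruned, drop = FALSE], ti)
    tibble::tibble(layer = nm, n_candidates = length(cand),
                   n_selected = length(pruned),
                   r_squared = fitrow$r_squared,
                   adj_r_squared = fitrow$adj_r_squared)
  })
  all_feats <- do.call(cbind, purrr::imap(selected, function(f, nm) {
    m <- layers[[nm]][, f, drop = FALSE]
    if (ncol(m) > 0) colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  }))
  combined <- fit_variance_model(all_feats, ti)
  structure(list(per_layer = per_layer, combined = combined,
                 selected = selected),
            class = "variance_report")
}

#' Randomization null for explained variance
#'
#' Draws `B` random feature sets of size `k` from a feature pool, applies
#' the same select / prune / fit procedure to each draw, and reports the
#' null distribution of adjusted R-squared plus the empirical p of an
#' observed value (add-one convention, so p is never 0).
#'
#' @param pool Subjects x features matrix to draw from.
#' @param k Features per draw (mirrors the size of the real layer).
#' @param ti Normalized TI vector.
#' @param observed Observed adjusted R-squared to compare against.
#' @param B Number of draws (default 1000).
#' @param alpha,threshold Passed to the select/prune steps.
#' @param seed RNG seed.
#' @return List: `null` (vector of B adjusted R-squared values),
#'   `summary` (one-row tibble: mean, q95, `empirical_p`).
#' @export
randomization_null <- function(pool, k, ti, observed, B = 1000,
                               alpha = 0.05, threshold = 0.4, seed = 1) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (ncol(pool) < k) {
    stop("pool (", ncol(pool), " features) smaller than k = ", k,
         call. = FALSE)
  }
  set.seed(seed)
  null <- vapply(seq_len(B), function(i) {
    feats <- sample(colnames(pool), k)
    layer <- pool[, feats, drop = FALSE]
    sel <- select_layer_features(layer, ti, alpha = alpha)
    cand <- sel$feature[sel$selected]
    if (length(cand) == 0) return(0)
    pruned <- prune_collinear(layer, cand, ti, threshold = threshold)
    fit_variance_model(layer[, pruned, drop = FALSE], ti)$adj_r_squared
  }, numeric(1))
  emp_p <- (1 + sum(null >= observed)) / (B + 1)
  list(null = null,
       summary = tibble::tibble(B = B, mean = mean(null),
                                q95 = stats::quantile(null, 0.95,
                                                      names = FALSE),
                                empirical_p = emp_p))
}

#' Polygenic risk score from SNP weights
#'
#' `score_s = sum_j beta_j dosage_js`; missing dosages are mean-imputed per
#' SNP (with a message).
#'
#' @param dosages SNPs x subjects dosage matrix.
#' @param weights Tibble with `snp_id` and `beta`.
#' @return Tibble: `subject_id`, `prs`.
#' @export
compute_prs <- function(dosages, weights) {
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("snp_id", "beta") %in% names(weights)))
  shared <- intersect(weights$snp_id, rownames(dosages))
  if (length(shared) == 0) {
    stop("no overlapping SNPs between weights and dosages", call. = FALSE)
  }
  d <- dosages[shared, , drop = FALSE]
  if (anyNA(d)) {
    message("mean-imputing ", sum(is.na(d)), " missing dosage value(s)")
    for (i in seq_len(nrow(d))) {
      v <- d[i, ]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      d[i, ] <- v
    }
  }
  b <- weights$beta[match(shared, weights$snp_id)]
  tibble::tibble(subject_id = colnames(d), prs = as.numeric(b %*% d))
}

#' Derive PRS weights from a marginal QTL scan on a training split
#'
#' Runs [qtl_scan()] of the TI outcome on a training subset of subjects and
#' keeps marginal betas with p < `alpha` as PRS weights.
#'
#' @param dosages SNPs x subjects matrix.
#' @param ti_tbl Tibble `subject_id`, `ti_norm`.
#' @param samples Sample sheet (for age/sex residualization).
#' @param train_subjects Subject ids forming the training split.
#' @param alpha Inclusion threshold (default 0.05).
#' @return Weights tibble (`snp_id`, `beta`) usable by [compute_prs()].
#' @export
prs_weights_from_scan <- function(dosages, ti_tbl, samples, train_subjects,
                                  alpha = 0.05) {
  ti_tbl <- tibble::as_tibble(ti_tbl)
  train <- intersect(train_subjects, ti_tbl$subject_id)
  pheno <- matrix(ti_tbl$ti_norm[match(train, ti_tbl$subject_id)],
                  ncol = 1, dimnames = list(train, "ti"))
  scan <- qtl_scan(dosages[, train, drop = FALSE], pheno,
                   samples = samples)
  keep <- !is.na(scan$p) & scan$p < alpha
  tibble::tibble(snp_id = scan$snp_id[keep], beta = scan$beta[keep])
}
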