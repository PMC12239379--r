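#' Classify methylation response trajectories
#'
#' Maps the sign pattern of the mean beta-value changes at T14 and T90
#' (both relative to T0) onto the four response shapes: `down_down`
#' (decreased at both), `down_up` (decreased at T14, increased at T90),
#' `up_down`, and `up_up`. An exact zero in either delta yields `flat`;
#' a missing delta yields `NA`.
#'
#' @param d14 Numeric vector of mean beta differences T14 - T0.
#' @param d90 Numeric vector of mean beta differences T90 - T0.
#' @param probe_id Optional probe ids.
#' @return Tibble: `probe_id` (if given), `d14`, `d90`, `class`.
#' @export
classify_trajectory <- function(d14, d90, probe_id = NULL) {
  stopifnot(length(d14) == length(d90))
  cls <- dplyr::case_when(
    is.na(d14) | is.na(d90) ~ NA_character_,
    d14 == 0 | d90 == 0 ~ "flat",
    d14 < 0 & d90 < 0 ~ "down_down",
    d14 < 0 & d90 > 0 ~ "down_up",
    d14 > 0 & d90 < 0 ~ "up_down",
    TRUE ~ "up_up"
  )
  out <- tibble::tibble(d14 = d14, d90 = d90, class = cls)
  if (!is.null(probe_id)) {
    out <- dplyr::bind_cols(tibble::tibble(probe_id = probe_id), out)
  }
  out
}

#' Mean beta deltas per probe between timepoints
#'
#' Convenience helper: subject-matched mean differences of beta values for
#' T14-T0 and T90-T0, the inputs of [classify_trajectory()].
#'
#' @param betas Probes x samples beta matrix.
#' @param samples Sample sheet.
#' @param probes Optional probe subset.
#' @return Tibble `probe_id`, `d14`, `d90`.
#' @export
beta_deltas <- function(betas, samples, probes = NULL) {
  samples <- tibble::as_tibble(samples)
  probe_set <- if (is.null(probes)) rownames(betas) else probes
  delta <- function(tp) {
    sa <- samples[samples$timepoint == "T0", ]
    sb <- samples[samples$timepoint == tp, ]
    shared <- intersect(sa$subject_id, sb$subject_id)
    rowMeans(betas[probe_set, sb$sample_id[match(shared, sb$subject_id)],
                   drop = FALSE] -
               betas[probe_set, sa$sample_id[match(shared, sa$subject_id)],
                     drop = FALSE], na.rm = TRUE)
  }
  tibble::tibble(probe_id = probe_set, d14 = delta("T14"), d90 = delta("T90"))
}

#' Classify baseline methylation state
#'
#' Tri-class partition of the mean baseline beta value: `hypo` below
#' `lower`, `hyper` above `upper`, `intermediate` otherwise. Thresholds
#' default to the conventional 0.3 / 0.7 partition and are configurable.
#'
#' @param beta_mean Numeric vector of mean baseline beta values.
#' @param lower,upper Class boundaries (defaults 0.3 and 0.7).
#' @return Character vector in `{hypo, intermediate, hyper}`.
#' @export
classify_baseline <- function(beta_mean, lower = 0.3, upper = 0.7) {
  dplyr::case_when(
    is.na(beta_mean) ~ NA_character_,
    beta_mean < lower ~ "hypo",
    beta_mean > upper ~ "hyper",
    TRUE ~ "intermediate"
  )
}

#' Fisher exact enrichment for a 2x2 table
#'
#' Two-sided Fisher exact test (probability-ordering rule) with the sample
#' odds ratio, e.g. methylation direction (increased/decreased) against
#' baseline state (hypo/hyper).
#'
#' @param table2x2 2x2 matrix of nonnegative integer counts.
#' @return One-row tibble: the four counts (`n11`..`n22`), `odds_ratio`
#'   (sample OR; `Inf`/0 at zero cells), `p`.
#' @export
fisher_enrichment <- function(table2x2) {
  tab <- as.matrix(table2x2)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble::tibble(n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1],
                 n22 = tab[2, 2], odds_ratio = or, p = p)
}

#' Direction-by-baseline enrichment over a probe table
#'
#' Builds, for each methylation-change direction, the 2x2 table of
#' direction (this one vs the others) against baseline class (hypo vs
#' hyper; intermediate probes excluded) and applies [fisher_enrichment()].
#'
#' @param probe_tbl Tibble with columns `direction`
#'   (`increased`/`decreased`) and `baseline_class` (from
#'   [classify_baseline()]).
#' @return Tibble with one row per (direction, focal baseline class).
#' @export
enrichment_by_direction <- function(probe_tbl) {
  df <- tibble::as_tibble(probe_tbl)
  stopifnot(all(c("direction", "baseline_class") %in% names(df)))
  df <- df[df$baseline_class %in% c("hypo", "hyper"), ]
  grid <- tidyr::expand_grid(direction = c("increased", "decreased"),
                             focal = c("hypo", "hyper"))
  purrr::pmap_dfr(grid, function(direction, focal) {
    tab <- matrix(c(
      sum(df$direction == direction & df$baseline_class == focal),
      sum(df$direction == direction & df$baseline_class != focal),
      sum(df$direction != direction & df$baseline_class == focal),
      sum(df$direction != direction & df$baseline_class != focal)
    ), 2, 2, byrow = TRUE)
    dplyr::bind_cols(tibble::tibble(direction = direction, focal = focal),
                     fisher_enrichment(tab))
  })
}

#' Spearman correlation of CpG changes with another data layer
#'
#' All pairwise Spearman correlations between per-subject CpG change
#' columns and layer feature columns (protein fold changes, hormone levels,
#' cell counts, ...), with BH-FDR across the grid. P-values follow
#' `stats::cor.test`: exact for small tie-free samples, t-approximation
#' with tie correction otherwise.
#'
#' @param cpg_changes Subjects x CpGs numeric matrix (rownames = subject).
#' @param layer Subjects x features numeric matrix, rows aligned by
#'   rowname intersection.
#' @param min_pairs Minimum complete pairs per correlation (default 10).
#' @return Tibble: `cpg`, `feature`, `n`, `rho`, `p`, `q` (constant pairs
#'   get NA with a `reason`).
#' @export
correlate_changes <- function(cpg_changes, layer, min_pairs = 10) {
  stopifnot(is.matrix(cpg_changes), is.matrix(layer))
  shared <- intersect(rownames(cpg_changes), rownames(layer))
  if (length(shared) < min_pairs) {
    stop("fewer than ", min_pairs, " shared subjects", call. = FALSE)
  }
  x <- cpg_changes[shared, , drop = FALSE]
  z <- layer[shared, , drop = FALSE]
  grid <- tidyr::expand_grid(cpg = colnames(x), feature = colnames(z))
  res <- purrr::pmap_dfr(grid, function(cpg, feature) {
    a <- x[, cpg]
    b <- z[, feature]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n < min_pairs) {
      return(tibble::tibble(cpg = cpg, feature = feature, n = n,
                            rho = NA_real_, p = NA_real_,
                            reason = "too_few_pairs"))
    }
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(tibble::tibble(cpg = cpg, feature = feature, n = n,
                            rho = NA_real_, p = NA_real_,
                            reason = "constant_vector"))
    }
    ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "spearman"))
    tibble::tibble(cpg = cpg, feature = feature, n = n,
                   rho = unname(ct$estimate), p = ct$p.value,
                   reason = NA_character_)
  })
  res$q <- bh_fdr(res$p)
  res
}

#' Replication check of association results
#'
#' Compares discovery and replication result tables on a shared probe set
#' and counts direction-consistent probes, nominally replicated probes
#' (replication p < 0.05 AND same direction), and FDR-replicated probes
#' (replication q < 0.05 AND same direction).
#'
#' @param discovery,replication `ewas_result`-style tibbles with
#'   `probe_id`, `estimate`, `p` (and optionally `q`).
#' @param probes Probe set to test (default: all discovery probes present
#'   in both).
#' @return One-row tibble: `n_tested`, `n_same_direction`, `n_nominal`,
#'   `n_fdr`.
#' @export
replication_check <- function(discovery, replication, probes = NULL) {
  if (is.null(probes)) probes <- discovery$probe_id
  probes <- intersect(probes, intersect(discovery$probe_id,
                                        replication$probe_id))
  if (length(probes) == 0) {
    stop("no overlapping probes between result sets", call. = FALSE)
  }
  d <- discovery[match(probes, discovery$probe_id), ]
  r <- replication[match(probes, replication$probe_id), ]
  ok <- !is.na(d$estimate) & !is.na(r$estimate)
  same <- ok & sign(d$estimate) == sign(r$estimate) & sign(d$estimate) != 0
  rq <- if ("q" %in% names(r)) r$q else bh_fdr(r$p)
  tibble::tibble(
    n_tested = length(probes),
    n_same_direction = sum(same),
    n_nominal = sum(same & !is.na(r$p) & r$p < 0.05),
    n_fdr = sum(same & !is.na(rq) & rq < 0.05)
  )
}
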