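#' QQ and volcano display of an EWAS result
#'
#' The default display is a QQ plot of the observed -log10 p-values
#' against the uniform expectation with the genomic inflation factor in
#' the subtitle; `type = "volcano"` plots effect size against -log10 p
#' with the suggestive threshold marked.
#'
#' @param object `ewas_result` tibble.
#' @param type `"qq"` or `"volcano"`.
#' @param suggestive Threshold line for the volcano (default 1e-5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ewas_result <- function(object, type = c("qq", "volcano"),
                                 suggestive = 1e-5, ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$p), ]
  if (type == "qq") {
    df <- df[order(df$p), ]
    df$expected <- -log10(stats::ppoints(nrow(df)))
    df$observed <- -log10(df$p)
    lam <- if (nrow(df) >= 100) compute_inflation(df$p) else NA_real_
    ggplot2::ggplot(df, ggplot2::aes(x = .data$expected,
                                     y = .data$observed)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(
        x = expression(Expected ~ -log[10](p)),
        y = expression(Observed ~ -log[10](p)),
        title = attr(object, "model_tag"),
        subtitle = if (!is.na(lam)) sprintf("lambda = %.3f", lam) else NULL
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                     y = -log10(.data$p))) +
      ggplot2::geom_point(size = 0.8, alpha = 0.6) +
      ggplot2::geom_hline(yintercept = -log10(suggestive), linetype = 2,
                          colour = "red") +
      ggplot2::labs(x = "Effect (M-value scale)",
                    y = expression(-log[10](p)),
                    title = attr(object, "model_tag")) +
      ggplot2::theme_minimal()
  }
}

#' Plot mean methylation trajectories by response class
#'
#' Mean beta value per timepoint for each probe, coloured by trajectory
#' class, one panel per class.
#'
#' @param betas Probes x samples beta matrix.
#' @param samples Sample sheet.
#' @param classes Tibble from [classify_trajectory()] (needs `probe_id`,
#'   `class`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(betas, samples, classes) {
  samples <- tibble::as_tibble(samples)
  df <- purrr::map_dfr(c("T0", "T14", "T90"), function(tp) {
    cols <- samples$sample_id[samples$timepoint == tp]
    tibble::tibble(probe_id = classes$probe_id, timepoint = tp,
                   mean_beta = rowMeans(betas[classes$probe_id, cols,
                                              drop = FALSE], na.rm = TRUE))
  })
  df <- dplyr::left_join(df, classes[, c("probe_id", "class")],
                         by = "probe_id")
  df$timepoint <- factor(df$timepoint, levels = c("T0", "T14", "T90"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$mean_beta,
                                   group = .data$probe_id,
                                   colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = NULL, y = "Mean beta value", colour = "Class") +
    ggplot2::theme_minimal()
}

#' Heatmap of PC-covariate associations
#'
#' Tile plot of -log10 p for each (principal component, covariate) pair
#' from [pca_covariate_scan()].
#'
#' @param scan A `pc_scan` object.
#' @return A ggplot object.
#' @export
plot_pc_scan <- function(scan) {
  df <- tibble::as_tibble(scan)
  df$neglogp <- -log10(df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$pc),
                                   y = .data$covariate,
                                   fill = .data$neglogp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(
      x = "Principal component", y = NULL,
      subtitle = sprintf("Top %d PCs capture %.1f%% of variance",
                         max(df$pc), 100 * attr(scan, "cum_var"))
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of variance explained per omics layer
#'
#' @param report A `variance_report` from [variance_explained()].
#' @return A ggplot object.
#' @export
plot_variance_explained <- function(report) {
  df <- tidy(report)
  df$layer <- factor(df$layer, levels = df$layer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer,
                                   y = .data$adj_r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = expression(Adjusted ~ R^2)) +
    ggplot2::theme_minimal()
}
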