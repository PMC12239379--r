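#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EWAS result
#'
#' @param x `ewas_result` tibble.
#' @param ... Unused.
#' @return Plain tibble of per-probe results.
#' @export
tidy.ewas_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an EWAS result
#'
#' @param x `ewas_result` tibble.
#' @param fdr,suggestive Significance thresholds (defaults 0.05 / 1e-5).
#' @param ... Unused.
#' @return Tibble: model tag, probes tested, counts below thresholds,
#'   genomic inflation lambda (NA when fewer than 100 p-values).
#' @export
glance.ewas_result <- function(x, fdr = 0.05, suggestive = 1e-5, ...) {
  p <- x$p[!is.na(x$p)]
  tibble::tibble(
    model_tag = attr(x, "model_tag") %||% NA_character_,
    n_probes = nrow(x),
    n_fdr_significant = sum(!is.na(x$q) & x$q < fdr),
    n_suggestive = sum(p < suggestive),
    lambda = if (length(p) >= 100) compute_inflation(p) else NA_real_
  )
}

#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total", "prop_mediated"),
    estimate = c(x$acme, x$ade, x$total, x$prop_mediated),
    conf_low = c(x$acme_lo, NA, NA, NA),
    conf_high = c(x$acme_hi, NA, NA, NA),
    p_value = c(x$acme_p, x$ade_p, x$total_p, NA)
  )
}

#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_sims = x$n_sims, acme = x$acme,
                 acme_p = x$acme_p, prop_mediated = x$prop_mediated,
                 prop_unstable = x$prop_unstable)
}

#' @export
tidy.variance_report <- function(x, ...) {
  dplyr::bind_rows(
    x$per_layer,
    dplyr::bind_cols(tibble::tibble(layer = "combined",
                                    n_candidates = NA_integer_,
                                    n_selected = x$combined$p_features),
                     x$combined[, c("r_squared", "adj_r_squared")])
  )
}

#' @export
glance.variance_report <- function(x, ...) {
  tibble::tibble(n = x$combined$n,
                 n_layers = nrow(x$per_layer),
                 combined_adj_r_squared = x$combined$adj_r_squared)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
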