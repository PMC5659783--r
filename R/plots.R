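#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot RT distributions of a behavioral dataset
#'
#' Histograms of reaction time (100-ms bins) faceted by unordered value
#' pair, with trial category mapped to fill.
#'
#' @param object An `ssm_dataset`.
#' @param binwidth Histogram bin width in ms.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssm_dataset
#' @export
autoplot.ssm_dataset <- function(object, binwidth = 100, ...) {
  d <- classify_trials(object, min_rt_ms = 0)
  d$pair <- sprintf("%d vs %d", d$v_lesser, d$v_greater)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rt_ms, fill = .data$category)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "stack") +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "Reaction time (ms)", y = "Trials", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a regression table
#'
#' Dot-and-whisker display of coefficient estimates with 95% intervals,
#' faceted by parameterization. RT tables show constant-normalized
#' coefficients (the reporting convention); the constant is omitted.
#'
#' @param object An `ssm_regression` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssm_regression
#' @export
autoplot.ssm_regression <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$term != "constant")
  is_rt <- !all(is.na(d$normalized))
  if (is_rt) {
    d$est <- d$normalized
    d$e_se <- d$se_normalized
  } else {
    d$est <- d$estimate
    d$e_se <- d$se
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$est)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$est - 1.96 * .data$e_se,
                                          ymax = .data$est + 1.96 * .data$e_se)) +
    ggplot2::facet_wrap(~parameterization, scales = "free_x") +
    ggplot2::labs(x = NULL,
                  y = if (is_rt) "Constant-normalized coefficient"
                      else "Coefficient (log-odds)") +
    ggplot2::theme_minimal()
}

#' Model-comparison bar chart
#'
#' Chi-square, AICc, and BIC of a set of fits, ordered by performance.
#'
#' @param fits List of [fit_model()] results.
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(fits) {
  d <- purrr::map_dfr(fits, glance) |>
    tidyr::pivot_longer(c("chi2", "aicc", "bic"), names_to = "criterion",
                        values_to = "value")
  d$model <- stats::reorder(d$model, -d$value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
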