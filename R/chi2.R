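# Bin masses implied by the 10/30/50/70/90% quantile cuts.
quantile_bin_masses <- function() diff(c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1))

# Side-independent categorization shared by quantile_table() and the
# chi-square binning of predicted datasets.
categorize_responded <- function(data, min_rt_ms = 300) {
  crossed <- if ("crossed" %in% names(data)) data$crossed else !is.na(data$choice)
  keep <- crossed & !is.na(data$choice) & !is.na(data$rt_ms) &
    data$rt_ms >= min_rt_ms
  d <- data[keep, , drop = FALSE]
  dplyr::mutate(
    d,
    v_lo = pmin(.data$v_left, .data$v_right),
    v_hi = pmax(.data$v_left, .data$v_right),
    v_chosen = ifelse(.data$choice == "L", .data$v_left, .data$v_right),
    category = dplyr::case_when(
      .data$v_lo == .data$v_hi ~ "all",
      .data$v_chosen == .data$v_hi ~ "hi",
      TRUE ~ "lo"
    ))
}

#' Chi-square contribution of one set of bins
#'
#' The Pearson-type contribution `n_eff * sum((p_obs - p_pred)^2 /
#' max(p_pred, p_floor))`, equivalent to `sum((O - E)^2 / E)` with expected
#' counts `E = n_eff * p_pred`.
#'
#' @param p_obs Observed bin proportions.
#' @param p_pred Predicted bin proportions.
#' @param n_eff Effective number of observations behind `p_obs`.
#' @param p_floor Floor applied to predicted proportions in the
#'   denominator.
#' @return Scalar chi-square contribution.
#' @export
chi2_bins <- function(p_obs, p_pred, n_eff, p_floor = 1e-4) {
  stopifnot(length(p_obs) == length(p_pred))
  n_eff * sum((p_obs - p_pred)^2 / pmax(p_pred, p_floor))
}

# Bin edges and observed masses for one summary row.
row_bins <- function(row) {
  if (!is.na(row$q10)) {
    list(edges = c(row$q10, row$q30, row$q50, row$q70, row$q90),
         p_obs = row$freq * quantile_bin_masses())
  } else {
    list(edges = NULL, p_obs = row$freq)
  }
}

#' Chi-square quantile objective
#'
#' Compares an observed choice/RT summary against model predictions. For
#' each input-value pair and each choice, the observed RT quantiles cut the
#' time line into six bins with observed masses
#' `(0.1, 0.2, 0.2, 0.2, 0.2, 0.1)` times the choice frequency
#' (frequency-only rows contribute a single bin); predicted masses are the
#' fraction of predicted trials falling into each bin. Each pair receives
#' equal weight through a common effective count `n_eff = (total responded
#' observed trials) / (number of pairs)`, and the total objective is the
#' sum of per-pair Pearson contributions (see [chi2_bins()]).
#'
#' @param observed An [quantile_table()] summary.
#' @param predicted Either a predicted trial-level dataset (e.g. from
#'   [simulate_dataset()]), filtered and categorized identically to the
#'   observed data, or a benchmark predictor from [null_predictor()] /
#'   [saturated_predictor()].
#' @param p_floor Floor on predicted proportions (guards empty predicted
#'   bins).
#' @return The chi-square statistic, with attribute `n_bins` giving the
#'   number of bin cells that entered the sum.
#' @export
chi2_statistic <- function(observed, predicted, p_floor = 1e-4) {
  stopifnot(inherits(observed, "ssm_quantiles"))
  n_eff <- attr(observed, "n_total") / attr(observed, "n_pairs")
  min_rt <- attr(observed, "min_rt_ms") %||% 300
  is_pred <- inherits(predicted, "ssm_predictor")
  if (!is_pred) {
    pd <- categorize_responded(predicted, min_rt_ms = min_rt)
  }
  pairs <- dplyr::distinct(observed, .data$v_lo, .data$v_hi)
  total <- 0
  n_bins <- 0L
  for (i in seq_len(nrow(pairs))) {
    rows <- observed[observed$v_lo == pairs$v_lo[i] &
                       observed$v_hi == pairs$v_hi[i], ]
    if (!is_pred) {
      cell <- pd[pd$v_lo == pairs$v_lo[i] & pd$v_hi == pairs$v_hi[i], ]
      n_cell <- nrow(cell)
    }
    p_obs_all <- c()
    p_pred_all <- c()
    for (j in seq_len(nrow(rows))) {
      row <- rows[j, ]
      bins <- row_bins(row)
      if (is_pred) {
        p_pred <- predict_cell(predicted, row, bins)
      } else {
        sub <- cell$rt_ms[cell$category == row$category]
        if (is.null(bins$edges)) {
          p_pred <- if (n_cell > 0) length(sub) / n_cell else 0
        } else if (n_cell == 0) {
          p_pred <- rep(0, 6)
        } else {
          idx <- findInterval(sub, bins$edges, left.open = TRUE) + 1L
          p_pred <- tabulate(idx, nbins = 6) / n_cell
        }
      }
      p_obs_all <- c(p_obs_all, bins$p_obs)
      p_pred_all <- c(p_pred_all, p_pred)
    }
    total <- total + chi2_bins(p_obs_all, p_pred_all, n_eff, p_floor)
    n_bins <- n_bins + length(p_obs_all)
  }
  structure(total, n_bins = n_bins)
}

# Predicted bin masses of a benchmark predictor for one summary row.
predict_cell <- function(predictor, row, bins) {
  freq <- predictor_freq(predictor, row)
  if (is.null(bins$edges)) return(freq)
  Fe <- predictor_cdf(predictor, row, bins$edges)
  freq * diff(c(0, Fe, 1))
}

predictor_freq <- function(predictor, row) {
  if (predictor$type == "null") {
    if (row$category == "all") return(1)
    if (row$category == "hi") return(predictor$freq_hi)
    return(1 - predictor$freq_hi)
  }
  key <- paste(row$v_lo, row$v_hi, sep = "|")
  cell <- predictor$cells[[key]]
  if (is.null(cell) || is.null(cell[[row$category]])) return(0)
  cell[[row$category]]$freq
}

predictor_cdf <- function(predictor, row, x) {
  if (predictor$type == "null") {
    lo <- predictor$rt_range[1]
    hi <- predictor$rt_range[2]
    return(pmin(1, pmax(0, (x - lo) / (hi - lo))))
  }
  key <- paste(row$v_lo, row$v_hi, sep = "|")
  cell <- predictor$cells[[key]]
  entry <- if (!is.null(cell)) cell[[row$category]] else NULL
  if (is.null(entry)) return(rep(0, length(x)))
  approx(entry$knots_x, entry$knots_p, xout = x, rule = 2,
         ties = list("ordered", max))$y
}

#' Benchmark predictors: saturated and null
#'
#' The saturated predictor reuses the training summary directly: each
#' cell's choice frequencies and a piecewise-linear RT distribution through
#' the five training quantiles (anchored at the cell minimum and maximum)
#' serve as the prediction, so its in-sample chi-square is exactly zero.
#' The null predictor assumes no input effects: a single mean choice
#' frequency across pairs and one uniform RT distribution spanning the
#' means of the per-cell RT minima and maxima.
#'
#' @param training An [quantile_table()] summary of the training data.
#' @return An object of class `ssm_predictor` accepted by
#'   [chi2_statistic()].
#' @export
saturated_predictor <- function(training) {
  stopifnot(inherits(training, "ssm_quantiles"))
  cells <- list()
  for (i in seq_len(nrow(training))) {
    row <- training[i, ]
    key <- paste(row$v_lo, row$v_hi, sep = "|")
    if (!is.na(row$q10)) {
      x <- c(row$rt_min, row$q10, row$q30, row$q50, row$q70, row$q90,
             row$rt_max)
      p <- c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)
    } else {
      x <- c(row$rt_min, row$rt_max)
      p <- c(0, 1)
      if (x[1] == x[2]) x[2] <- x[2] + 1e-9
    }
    cells[[key]][[row$category]] <- list(freq = row$freq, knots_x = x,
                                         knots_p = p)
  }
  structure(list(type = "saturated", cells = cells), class = "ssm_predictor")
}

#' @rdname saturated_predictor
#' @export
null_predictor <- function(training) {
  stopifnot(inherits(training, "ssm_quantiles"))
  unequal <- dplyr::filter(training, .data$v_lo != .data$v_hi)
  freq_hi <- unequal |>
    dplyr::group_by(.data$v_lo, .data$v_hi) |>
    dplyr::summarise(
      f = sum(.data$freq[.data$category == "hi"]), .groups = "drop") |>
    dplyr::pull(.data$f) |>
    mean()
  structure(list(type = "null",
                 freq_hi = freq_hi,
                 rt_range = c(mean(training$rt_min), mean(training$rt_max))),
            class = "ssm_predictor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
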