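#' Choice-frequency and RT-quantile summary
#'
#' Reduces a trial-level dataset to the summary statistics used by the
#' chi-square quantile objective: for each unordered input-value pair, the
#' frequency of each choice and the 10/30/50/70/90% RT quantiles of that
#' choice's RT distribution (six bins). Quantiles use linear interpolation
#' between order statistics (R type 7).
#'
#' Trials are dropped if they did not cross threshold or if RT falls below
#' the fast-contaminant cutoff (`min_rt_ms`, default 300 ms). For unequal
#' pairs, choices are categorized side-independently as `"hi"` (the
#' greater-valued option chosen) or `"lo"`; equal-value pairs carry no
#' choice information and form a single `"all"` category. Choices with
#' fewer than `min_quantile_n` trials in a cell contribute their frequency
#' only (no quantiles).
#'
#' @param data Trial-level data frame (`v_left`, `v_right`, `choice`,
#'   `rt_ms`, optionally `crossed`).
#' @param min_rt_ms Fast-contaminant cutoff in ms.
#' @param min_quantile_n Minimum trials per choice for RT quantiles.
#' @return An `ssm_quantiles` tibble with one row per (pair, choice):
#'   `v_lo`, `v_hi`, `category`, `n`, `freq`, `q10`..`q90`, `rt_min`,
#'   `rt_max`. Attributes `n_total` (responded trials) and `n_pairs`.
#' @export
quantile_table <- function(data, min_rt_ms = 300, min_quantile_n = 5) {
  stopifnot(nrow(data) > 0)
  crossed <- if ("crossed" %in% names(data)) data$crossed else !is.na(data$choice)
  keep <- crossed & !is.na(data$choice) & !is.na(data$rt_ms) &
    data$rt_ms >= min_rt_ms
  d <- data[keep, , drop = FALSE]
  if (nrow(d) == 0) stop("no responded trials after filtering", call. = FALSE)
  d <- dplyr::mutate(
    d,
    v_lo = pmin(.data$v_left, .data$v_right),
    v_hi = pmax(.data$v_left, .data$v_right),
    v_chosen = ifelse(.data$choice == "L", .data$v_left, .data$v_right),
    category = dplyr::case_when(
      .data$v_lo == .data$v_hi ~ "all",
      .data$v_chosen == .data$v_hi ~ "hi",
      TRUE ~ "lo"
    ))
  pair_n <- d |>
    dplyr::count(.data$v_lo, .data$v_hi, name = "n_pair")
  tab <- d |>
    dplyr::group_by(.data$v_lo, .data$v_hi, .data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      q10 = quantile(.data$rt_ms, 0.1, names = FALSE),
      q30 = quantile(.data$rt_ms, 0.3, names = FALSE),
      q50 = quantile(.data$rt_ms, 0.5, names = FALSE),
      q70 = quantile(.data$rt_ms, 0.7, names = FALSE),
      q90 = quantile(.data$rt_ms, 0.9, names = FALSE),
      rt_min = min(.data$rt_ms),
      rt_max = max(.data$rt_ms),
      .groups = "drop") |>
    dplyr::left_join(pair_n, by = c("v_lo", "v_hi")) |>
    dplyr::mutate(freq = .data$n / .data$n_pair) |>
    dplyr::select(-"n_pair")
  qcols <- c("q10", "q30", "q50", "q70", "q90")
  tab[tab$n < min_quantile_n, qcols] <- NA_real_
  tab <- dplyr::arrange(tab, .data$v_lo, .data$v_hi, .data$category) |>
    dplyr::relocate("freq", .after = "n")
  structure(tab,
            n_total = nrow(d),
            n_pairs = nrow(pair_n),
            min_rt_ms = min_rt_ms,
            class = c("ssm_quantiles", class(tab)))
}

#' Deterministic parity split into training and test halves
#'
#' Assigns odd-numbered trials from odd-numbered subjects and even-numbered
#' trials from even-numbered subjects to the training half; the remaining
#' trials form the test half. The split is deterministic, idempotent, and
#' exhaustive.
#'
#' @param data Trial-level data frame with integer `subject` and `trial`
#'   columns.
#' @return A list with elements `training` and `test`.
#' @export
parity_split <- function(data) {
  if (!all(c("subject", "trial") %in% names(data))) {
    stop("parity_split() needs `subject` and `trial` columns", call. = FALSE)
  }
  train <- (data$subject %% 2 == 1) == (data$trial %% 2 == 1)
  list(training = data[train, , drop = FALSE],
       test = data[!train, , drop = FALSE])
}
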