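#' Classify trials as correct, incorrect, or indifferent
#'
#' Correct trials chose the option with greater rated value, incorrect
#' trials chose the lesser-valued option, and indifferent trials offered
#' two options of equal value (accuracy is undefined for them).
#' Non-responses and fast contaminants (RT below `min_rt_ms`) are dropped.
#'
#' @param data Trial-level data frame (`v_left`, `v_right`, `choice`,
#'   `rt_ms`).
#' @param min_rt_ms Fast-contaminant cutoff in ms.
#' @return The filtered data with added columns `v_chosen`, `v_greater`,
#'   `v_lesser`, and `category` (`"correct"`, `"incorrect"`,
#'   `"indifferent"`).
#' @export
classify_trials <- function(data, min_rt_ms = 300) {
  crossed <- if ("crossed" %in% names(data)) data$crossed else !is.na(data$choice)
  keep <- crossed & !is.na(data$choice) & !is.na(data$rt_ms) &
    data$rt_ms >= min_rt_ms
  d <- data[keep, , drop = FALSE]
  dplyr::mutate(
    d,
    v_chosen = ifelse(.data$choice == "L", .data$v_left, .data$v_right),
    v_greater = pmax(.data$v_left, .data$v_right),
    v_lesser = pmin(.data$v_left, .data$v_right),
    category = dplyr::case_when(
      .data$v_left == .data$v_right ~ "indifferent",
      .data$v_chosen == .data$v_greater ~ "correct",
      TRUE ~ "incorrect"
    ))
}

#' Normalize rating values to the unit interval
#'
#' Maps the rating scale linearly so that its minimum becomes 0 and its
#' maximum becomes 1 (e.g. the 4-level scale `{1, 2, 3, 4}` maps to
#' `{0, 1/3, 2/3, 1}`), enabling comparison of regression coefficients
#' across datasets with different scales. The map is idempotent on
#' already-normalized data.
#'
#' @param data Trial-level data frame; all of `v_left`, `v_right`,
#'   `v_chosen`, `v_greater`, `v_lesser` present are transformed.
#' @param levels The rating scale; defaults to the sorted distinct values
#'   observed in `v_left`/`v_right`.
#' @return The data with value columns rescaled.
#' @export
normalize_values <- function(data, levels = NULL) {
  if (is.null(levels)) {
    levels <- sort(unique(c(data$v_left, data$v_right)))
  }
  if (length(unique(levels)) < 2) {
    stop("need at least two distinct rating levels", call. = FALSE)
  }
  lo <- min(levels); hi <- max(levels)
  for (col in intersect(c("v_left", "v_right", "v_chosen", "v_greater",
                          "v_lesser"), names(data))) {
    data[[col]] <- (data[[col]] - lo) / (hi - lo)
  }
  data
}

regression_row <- function(outcome, parameterization, fit, term_map, n) {
  sm <- summary(fit)$coefficients
  est <- unname(sm[, 1]); se <- unname(sm[, 2])
  stat <- unname(sm[, 3]); p <- unname(sm[, 4])
  terms <- unname(term_map[rownames(sm)])
  intercept <- est[terms == "constant"]
  is_rt <- outcome != "accuracy"
  tibble::tibble(
    outcome = outcome,
    parameterization = parameterization,
    term = terms,
    estimate = est,
    se = se,
    statistic = stat,
    p_value = p,
    normalized = if (is_rt) {
      ifelse(terms == "constant", est, est / intercept)
    } else NA_real_,
    se_normalized = if (is_rt) {
      ifelse(terms == "constant", se, se / intercept)
    } else NA_real_,
    n = n
  )
}

new_ssm_regression <- function(x, flagged = FALSE) {
  structure(x, flagged = flagged,
            class = c("ssm_regression", class(tibble::tibble())))
}

#' Complementary logistic regressions of choice accuracy
#'
#' Excluding indifferent trials, fits two complementary logistic models of
#' the probability of choosing the greater-valued option: one on the
#' (normalized) greater and lesser values individually, and one on the
#' absolute value difference and the value sum, which are orthogonal
#' linear recombinations of the same inputs. A positive sum effect is the
#' signature of attentional overweighting of the greater value.
#'
#' @param data Output of [classify_trials()], value-normalized via
#'   [normalize_values()].
#' @return An `ssm_regression` tibble with both parameterizations
#'   (`outcome = "accuracy"`); coefficients are on the log-odds scale. If
#'   the fit separates perfectly the result is flagged
#'   (`attr(, "flagged")`) and coefficients are `NA`.
#' @export
fit_accuracy <- function(data) {
  d <- dplyr::filter(data, .data$category != "indifferent")
  d <- dplyr::mutate(d,
                     correct = as.integer(.data$category == "correct"),
                     vdiff = .data$v_greater - .data$v_lesser,
                     vsum = .data$v_greater + .data$v_lesser)
  sep <- FALSE
  fits <- withCallingHandlers(
    list(
      gl = glm(correct ~ v_greater + v_lesser, binomial(), data = d),
      ds = glm(correct ~ vdiff + vsum, binomial(), data = d)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  out <- dplyr::bind_rows(
    regression_row("accuracy", "greater+lesser", fits$gl,
                   c("(Intercept)" = "constant", v_greater = "greater",
                     v_lesser = "lesser"), nrow(d)),
    regression_row("accuracy", "difference+sum", fits$ds,
                   c("(Intercept)" = "constant", vdiff = "difference",
                     vsum = "sum"), nrow(d)))
  if (sep) {
    out$estimate <- NA_real_
    out$se <- NA_real_
    out$statistic <- NA_real_
    out$p_value <- NA_real_
  }
  new_ssm_regression(out, flagged = sep)
}

#' Complementary linear regressions of reaction time
#'
#' Fits least-squares models of RT in seconds within one trial category.
#' For correct and incorrect choices the same two complementary
#' parameterizations as in [fit_accuracy()] are used; for indifferent
#' choices (zero difference by definition) a single model on the value sum
#' suffices. Following the reporting convention for RT effects, each
#' non-constant coefficient is also expressed as a fraction of the mean by
#' dividing it (and its standard error) by the constant term, which is
#' reported raw in seconds: a normalized coefficient of -0.1 means a 10%
#' speed-up at that regressor's maximum, all else equal.
#'
#' @param data Output of [classify_trials()], value-normalized.
#' @param category `"correct"`, `"incorrect"`, or `"indifferent"`.
#' @param min_n Minimum trials required; below it the result is flagged
#'   and empty.
#' @return An `ssm_regression` tibble (`outcome = "rt_<category>"`) with
#'   raw (`estimate`, `se`) and constant-normalized (`normalized`,
#'   `se_normalized`) coefficients.
#' @export
fit_rt <- function(data, category = c("correct", "incorrect", "indifferent"),
                   min_n = 10) {
  category <- match.arg(category)
  d <- dplyr::filter(data, .data$category == !!category)
  outcome <- paste0("rt_", category)
  if (nrow(d) < min_n) {
    return(new_ssm_regression(
      tibble::tibble(outcome = character(0), parameterization = character(0),
                     term = character(0), estimate = numeric(0),
                     se = numeric(0), statistic = numeric(0),
                     p_value = numeric(0), normalized = numeric(0),
                     se_normalized = numeric(0), n = integer(0)),
      flagged = TRUE))
  }
  d <- dplyr::mutate(d,
                     rt_s = .data$rt_ms / 1000,
                     vdiff = .data$v_greater - .data$v_lesser,
                     vsum = .data$v_greater + .data$v_lesser)
  if (category == "indifferent") {
    fit <- lm(rt_s ~ vsum, data = d)
    out <- regression_row(outcome, "sum-only", fit,
                          c("(Intercept)" = "constant", vsum = "sum"),
                          nrow(d))
    return(new_ssm_regression(out))
  }
  gl <- lm(rt_s ~ v_greater + v_lesser, data = d)
  ds <- lm(rt_s ~ vdiff + vsum, data = d)
  out <- dplyr::bind_rows(
    regression_row(outcome, "greater+lesser", gl,
                   c("(Intercept)" = "constant", v_greater = "greater",
                     v_lesser = "lesser"), nrow(d)),
    regression_row(outcome, "difference+sum", ds,
                   c("(Intercept)" = "constant", vdiff = "difference",
                     vsum = "sum"), nrow(d)))
  new_ssm_regression(out)
}

#' Contrast of absolute coefficient magnitudes
#'
#' Compares the magnitudes of two coefficients from the same model,
#' irrespective of sign: `M = |b1| - |b2|`, tested two-tailed against zero
#' with combined standard errors.
#'
#' @param est1,se1 First coefficient and its standard error.
#' @param est2,se2 Second coefficient and its standard error.
#' @return A tibble with `m` (difference of absolute values), `se`,
#'   `statistic`, `p_value`.
#' @export
abs_contrast <- function(est1, se1, est2, se2) {
  m <- abs(est1) - abs(est2)
  se <- sqrt(se1^2 + se2^2)
  z <- m / se
  tibble::tibble(m = m, se = se, statistic = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Compare mean RT between two trial categories
#'
#' Two-tailed Welch two-sample t test of mean RT (ms) between categories
#' (e.g. incorrect vs correct choices).
#'
#' @param data Output of [classify_trials()].
#' @param cat_a,cat_b Category labels; the reported difference is
#'   `mean(cat_a) - mean(cat_b)`.
#' @return A tibble with `mean_diff_ms`, `statistic`, `df`, `p_value`.
#' @export
category_rt_test <- function(data, cat_a, cat_b) {
  a <- data$rt_ms[data$category == cat_a]
  b <- data$rt_ms[data$category == cat_b]
  stopifnot(length(a) > 1, length(b) > 1)
  tt <- t.test(a, b)
  tibble::tibble(mean_diff_ms = mean(a) - mean(b),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Trial-weighted aggregation of regression tables
#'
#' Meta-analytic pooling across datasets: coefficient-wise weighted means
#' with weights proportional to each table's trial count, and an aggregate
#' standard error derived from the weighted between-dataset variance of
#' the estimates. All tables must share outcome and parameterization; a
#' single table is returned unchanged.
#'
#' @param tables List of `ssm_regression` tibbles from the same analysis.
#' @param weights Optional numeric weights; defaults to each table's `n`.
#' @return An aggregated `ssm_regression` tibble.
#' @export
meta_aggregate <- function(tables, weights = NULL) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  if (is.null(weights)) {
    weights <- vapply(tables, function(t) as.numeric(t$n[1]), numeric(1))
  }
  key <- lapply(tables, function(t) t[c("outcome", "parameterization", "term")])
  if (!all(vapply(key, identical, logical(1), y = key[[1]]))) {
    stop("all tables must share outcome, parameterization, and terms",
         call. = FALSE)
  }
  w <- weights / sum(weights)
  k <- length(tables)
  agg <- key[[1]]
  pool <- function(col) {
    mat <- vapply(tables, function(t) t[[col]], numeric(nrow(agg)))
    est <- drop(mat %*% w)
    var_b <- drop(((mat - est)^2) %*% w) * k / (k - 1)
    list(mean = est, se = sqrt(var_b / k))
  }
  pe <- pool("estimate")
  agg$estimate <- pe$mean
  agg$se <- pe$se
  agg$statistic <- agg$estimate / agg$se
  agg$p_value <- 2 * pnorm(-abs(agg$statistic))
  if (!all(is.na(tables[[1]]$normalized))) {
    pn <- pool("normalized")
    agg$normalized <- pn$mean
    agg$se_normalized <- pn$se
  } else {
    agg$normalized <- NA_real_
    agg$se_normalized <- NA_real_
  }
  agg$n <- sum(vapply(tables, function(t) as.integer(t$n[1]), integer(1)))
  new_ssm_regression(tibble::as_tibble(agg))
}
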