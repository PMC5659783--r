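# Standard-normal deviates via Box-Muller on R's uniform stream, consuming
# one uniform pair per two deviates (the trailing deviate is discarded for
# odd m). Matches the draw order of the compiled core exactly, so the R and
# C++ simulation routes are bit-identical under a shared seed.
rnorm_bm <- function(m) {
  n_pairs <- ceiling(m / 2)
  out <- numeric(2 * n_pairs)
  for (i in seq_len(n_pairs)) {
    u <- runif(2)
    r <- sqrt(-2 * log(u[1]))
    th <- 2 * pi * u[2]
    out[2 * i - 1] <- r * cos(th)
    out[2 * i] <- r * sin(th)
  }
  out[seq_len(m)]
}

#' Simulate a single trial (pure-R reference path)
#'
#' Iterates the rectified stochastic recurrence from `t = 0` until the
#' first decision signal reaches the threshold `D` or the horizon expires.
#' Baseline input and noise act from stimulus onset, before the value
#' signals switch on at `T0`, so starting-point variability emerges from
#' predecision noise accumulation. The reported RT is the post-update time
#' of the first crossing; simultaneous crossings are broken uniformly at
#' random.
#'
#' This reference implementation is built from [value_signal()],
#' [drift_increment()] and [update_state()] and consumes R's RNG in the
#' same order as the compiled batch path used by [simulate_dataset()], so
#' the two agree exactly under a shared seed.
#'
#' @param params An [ssm_params()] object.
#' @param values Numeric vector of latent option values.
#' @param config An [ssm_config()] object.
#' @return A one-row tibble with `choice` (alternative index, `NA` if no
#'   crossing), `rt_ms`, and `crossed`.
#' @export
simulate_trial <- function(params, values, config = ssm_config()) {
  m <- length(values)
  state <- list(d = rep(0, m), t_ms = 0)
  max_steps <- round(config$t_max_ms / config$dt_ms)
  for (step in seq_len(max_steps)) {
    v <- value_signal(values, state$t_ms, params, config)
    f <- drift_increment(params, v, state$d)
    eps <- params$sigma * rnorm_bm(m)
    state <- update_state(state, f, eps, config$dt_ms)
    hits <- which(state$d >= config$threshold)
    if (length(hits) > 0) {
      win <- if (length(hits) == 1) hits else {
        hits[floor(runif(1) * length(hits)) + 1]
      }
      return(tibble::tibble(choice = win, rt_ms = state$t_ms, crossed = TRUE))
    }
  }
  tibble::tibble(choice = NA_integer_, rt_ms = NA_real_, crossed = FALSE)
}

#' Simulate a behavioral dataset over a trial design
#'
#' Runs every trial of `design` through the compiled accumulator core and
#' returns a trial-level tibble. Reproducible given `seed`; all randomness
#' flows through R's RNG.
#'
#' @param params An [ssm_params()] object.
#' @param design A data frame with columns `v_left` and `v_right` (positive
#'   integer latent values), one row per trial; optional `subject` and
#'   `trial` columns are carried through (defaults: subject 1, trial =
#'   row number). See [design_grid()] and [make_design()].
#' @param config An [ssm_config()] object.
#' @param seed Optional integer seed set before simulating.
#' @return An `ssm_dataset` tibble with columns `subject`, `trial`,
#'   `v_left`, `v_right`, `choice` (`"L"`/`"R"`/`NA`), `rt_ms`, `crossed`,
#'   carrying provenance (model, parameters, seed) as attributes.
#' @examples
#' d <- simulate_dataset(reference_params("NDD"),
#'                       design_grid(1:4, 50), seed = 1)
#' dplyr::count(d, v_left, v_right)
#' @export
simulate_dataset <- function(params, design, config = ssm_config(),
                             seed = NULL) {
  stopifnot(inherits(params, "ssm_params"),
            all(c("v_left", "v_right") %in% names(design)),
            nrow(design) > 0,
            all(design$v_left > 0), all(design$v_right > 0))
  if (!is.null(seed)) set.seed(seed)
  pv <- param_vector(params)
  res <- sim_trials_cpp(
    model_code(params$model),
    pv[["b"]], pv[["g"]], pv[["sigma"]], pv[["i_v"]], pv[["s"]],
    pv[["i_d"]], pv[["a"]],
    cbind(design$v_left, design$v_right),
    config$threshold, config$dt_ms, config$t0_ms, config$t_max_ms)
  out <- tibble::tibble(
    subject = if ("subject" %in% names(design)) design$subject else 1L,
    trial = if ("trial" %in% names(design)) design$trial
            else seq_len(nrow(design)),
    v_left = design$v_left,
    v_right = design$v_right,
    choice = c("L", "R")[res$choice],
    rt_ms = res$rt_ms,
    crossed = res$crossed
  )
  new_ssm_dataset(out, provenance = list(
    origin = "simulated", model = params$model,
    params = unclass(params)[setdiff(names(params), "model")],
    seed = seed))
}

new_ssm_dataset <- function(x, provenance = list(origin = "unknown")) {
  structure(tibble::as_tibble(x),
            provenance = provenance,
            class = c("ssm_dataset", class(tibble::tibble())))
}

#' Balanced grid of input vectors
#'
#' Expands every unordered pair of the given value levels (10 pairs for 4
#' levels, equal-value pairs included) into `trials_per_vector` trials,
#' with the side of the greater value counterbalanced across the
#' repetitions of each unequal pair. Deterministic; use [make_design()] for
#' a randomized trial sequence.
#'
#' @param values Integer value levels (default `1:4`).
#' @param trials_per_vector Repetitions of each unordered pair.
#' @return A tibble with columns `v_left`, `v_right`.
#' @export
design_grid <- function(values = 1:4, trials_per_vector = 2000) {
  pairs <- tidyr::expand_grid(v_lo = values, v_hi = values) |>
    dplyr::filter(.data$v_lo <= .data$v_hi)
  purrr::pmap_dfr(pairs, function(v_lo, v_hi) {
    n <- trials_per_vector
    hi_left <- rep(c(TRUE, FALSE), length.out = n)
    tibble::tibble(v_left = ifelse(hi_left, v_hi, v_lo),
                   v_right = ifelse(hi_left, v_lo, v_hi))
  })
}

#' Write and read behavioral datasets as delimited text
#'
#' Datasets are stored as comma-separated text with a header row; comment
#' lines prefixed `#` carry the provenance (origin, model, parameter
#' fingerprint, seed) of simulated data.
#'
#' @param data An `ssm_dataset` (or any trial-level data frame with the
#'   standard columns).
#' @param path File path.
#' @return `write_behavior()` returns `path` invisibly; `read_behavior()`
#'   returns an `ssm_dataset`.
#' @export
write_behavior <- function(data, path) {
  prov <- attr(data, "provenance")
  hdr <- character(0)
  if (!is.null(prov)) {
    hdr <- c(hdr, sprintf("# origin: %s", prov$origin))
    if (!is.null(prov$model)) hdr <- c(hdr, sprintf("# model: %s", prov$model))
    if (!is.null(prov$params)) {
      fp <- paste(sprintf("%s=%.17g", names(prov$params),
                          unlist(prov$params)), collapse = " ")
      hdr <- c(hdr, sprintf("# params: %s", fp))
    }
    if (!is.null(prov$seed)) hdr <- c(hdr, sprintf("# seed: %d", prov$seed))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr) > 0) writeLines(hdr, con)
  utils::write.table(as.data.frame(data), con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  lines <- readLines(path)
  cmt <- lines[startsWith(lines, "#")]
  prov <- list(origin = "file")
  for (ln in cmt) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]+:", "", kv))
    prov[[key]] <- val
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  dat$choice <- as.character(dat$choice)
  new_ssm_dataset(dat, provenance = prov)
}
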