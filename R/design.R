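#' Randomized balanced trial sequence for one subject
#'
#' Builds a trial sequence in the style of the emulated food-choice task:
#' every unordered pair of the rating levels appears equally often
#' (trials are divided as evenly as possible across the 10 pairs of a
#' 4-level scale, which also balances the value differences from 0 to 3),
#' the side of the greater value is counterbalanced within each unequal
#' pair (half-and-half up to rounding), the order is randomized, and —
#' optionally — no identical value pair occurs on consecutive trials.
#'
#' @param values Integer rating levels (default `1:4`).
#' @param n_trials Trials in the sequence (default 720).
#' @param seed Integer seed; the sequence is deterministic given it.
#' @param no_repeat Forbid identical consecutive value pairs.
#' @return A tibble with columns `trial`, `v_left`, `v_right`.
#' @export
make_design <- function(values = 1:4, n_trials = 720, seed = 1,
                        no_repeat = TRUE) {
  set.seed(seed)
  pairs <- tidyr::expand_grid(v_lo = values, v_hi = values) |>
    dplyr::filter(.data$v_lo <= .data$v_hi)
  n_pairs <- nrow(pairs)
  reps <- rep(n_trials %/% n_pairs, n_pairs)
  extra <- n_trials %% n_pairs
  if (extra > 0) {
    idx <- sample.int(n_pairs, extra)
    reps[idx] <- reps[idx] + 1
  }
  trials <- purrr::pmap_dfr(
    list(pairs$v_lo, pairs$v_hi, reps),
    function(v_lo, v_hi, n) {
      hi_left <- sample(rep(c(TRUE, FALSE), length.out = n))
      tibble::tibble(v_left = ifelse(hi_left, v_hi, v_lo),
                     v_right = ifelse(hi_left, v_lo, v_hi))
    })
  n <- nrow(trials)
  for (attempt in seq_len(50)) {
    ord <- sample.int(n)
    cand <- trials[ord, ]
    if (!no_repeat) break
    # left-to-right repair: swap each repeat with a later trial whose pair
    # differs from both new neighborhoods; reshuffle if a repeat resists
    pid <- paste(pmin(cand$v_left, cand$v_right),
                 pmax(cand$v_left, cand$v_right))
    at <- function(k) if (k >= 1 && k <= n) pid[k] else ""
    clean <- TRUE
    for (i in seq.int(2L, n)) {
      if (pid[i] != pid[i - 1L]) next
      js <- setdiff(seq.int(i + 1L, length.out = max(0L, n - i)), i)
      js <- js[vapply(js, function(j) {
        pid[j] != at(i - 1L) && pid[j] != at(i + 1L) &&
          pid[i] != at(j - 1L) && pid[i] != at(j + 1L) && j != i + 1L
      }, logical(1))]
      if (length(js) == 0) {
        clean <- FALSE
        break
      }
      j <- js[sample.int(length(js), 1)]
      cand[c(i, j), ] <- cand[c(j, i), ]
      pid[c(i, j)] <- pid[c(j, i)]
    }
    if (clean) break
  }
  trials <- cand
  tibble::tibble(trial = seq_len(nrow(trials)),
                 v_left = trials$v_left, v_right = trials$v_right)
}

#' Generate a full synthetic study
#'
#' Composes [make_design()] and [simulate_dataset()] into a multi-subject
#' synthetic experiment suitable for [parity_split()], fitting, and the
#' regression battery. Each subject receives an independently randomized
#' balanced sequence; per-subject seeds derive deterministically from
#' `seed`.
#'
#' @param params An [ssm_params()] object (the generating model).
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject.
#' @param values Rating levels.
#' @param config An [ssm_config()] object.
#' @param seed Master seed.
#' @return An `ssm_dataset` with `subject` and `trial` columns and
#'   simulation provenance.
#' @export
generate_study <- function(params, n_subjects = 31, n_trials = 720,
                           values = 1:4, config = ssm_config(), seed = 1) {
  out <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    des <- make_design(values, n_trials,
                       seed = (seed * 10007 + s) %% .Machine$integer.max)
    des$subject <- s
    simulate_dataset(params, des, config,
                     seed = (seed * 20011 + s) %% .Machine$integer.max)
  })
  new_ssm_dataset(out, provenance = list(
    origin = "simulated", model = params$model,
    params = unclass(params)[setdiff(names(params), "model")],
    seed = seed))
}
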