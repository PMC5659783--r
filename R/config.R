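#' Simulation configuration
#'
#' Fixed constants of the discrete-time accumulator framework: the response
#' threshold `D` (an arbitrary scaling constant, 100 by convention), the
#' time step (10 ms), the predecision onset time of the value signals
#' (150 ms, biologically constrained rather than fitted), the simulation
#' horizon (3000 ms, the response window of the emulated task), and the
#' number of alternatives.
#'
#' @param threshold Activation level `D` that triggers a response.
#' @param dt_ms Time step in ms.
#' @param t0_ms Predecision onset of the value signals in ms; must be a
#'   multiple of `dt_ms`.
#' @param t_max_ms Simulation horizon in ms; trials that have not crossed
#'   threshold by this time are flagged as non-responses.
#' @param n_alternatives Number of choice alternatives (2 for the paradigm
#'   the models were developed for; the general equations support more).
#' @return An object of class `ssm_config`.
#' @export
ssm_config <- function(threshold = 100, dt_ms = 10, t0_ms = 150,
                       t_max_ms = 3000, n_alternatives = 2L) {
  stopifnot(threshold > 0, dt_ms > 0, t0_ms >= 0, t0_ms < t_max_ms,
            n_alternatives >= 2)
  if (abs(t0_ms / dt_ms - round(t0_ms / dt_ms)) > 1e-9) {
    stop("t0_ms must be an integer multiple of dt_ms", call. = FALSE)
  }
  structure(list(threshold = threshold, dt_ms = dt_ms, t0_ms = t0_ms,
                 t_max_ms = t_max_ms,
                 n_alternatives = as.integer(n_alternatives)),
            class = "ssm_config")
}

#' @export
print.ssm_config <- function(x, ...) {
  cat(sprintf(
    "<ssm_config> D = %g, dt = %g ms, T0 = %g ms, horizon = %g ms, %d alternatives\n",
    x$threshold, x$dt_ms, x$t0_ms, x$t_max_ms, x$n_alternatives))
  invisible(x)
}
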