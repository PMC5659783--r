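#' Value signal at a given time
#'
#' The input to each accumulator is a step function: zero before the
#' predecision time `T0`, and the latent value thereafter. Under the SSCA
#' model the latent values are passed through the supralinear power law
#' `V^a`, a static approximation of attention's winner-take-all positive
#' feedback; all other models use the values as given.
#'
#' @param values Numeric vector of latent option values (positive).
#' @param t_ms Time since stimulus onset in ms.
#' @param params An [ssm_params()] object.
#' @param config An [ssm_config()] object.
#' @return Numeric vector of value signals, one per alternative.
#' @examples
#' p <- reference_params("SSCA")
#' value_signal(c(4, 1), 200, p)  # c(4^1.373, 1)
#' @export
value_signal <- function(values, t_ms, params, config = ssm_config()) {
  stopifnot(t_ms >= 0, all(values > 0))
  if (t_ms < config$t0_ms) return(rep(0, length(values)))
  if (params$model == "SSCA") values^params$a else as.numeric(values)
}

#' Deterministic per-step drift increment
#'
#' The noise-free part of each model's update: the model-specific term
#' `f_x(t)` including baseline input, value-signal input with any
#' input-dependent competition, and any state-dependent lateral inhibition.
#' Per alternative `x` (sums over `y != x` unless noted):
#' \describe{
#'   \item{RACE}{`b + g v_x`}
#'   \item{NDD}{`b + g (v_x - mean of the other v)`}
#'   \item{SNFI}{`b + g (v_x - i_v sum v_y)`}
#'   \item{DNFI}{`g (b + v_x) / (s + sum over all y of v_y)`}
#'   \item{CA}{`b + g v_x - i_d sum d_y`}
#'   \item{SCA, SSCA}{`b + g (v_x - i_v sum v_y) - i_d sum d_y`}
#'   \item{DCA}{`g (b + v_x) / (s + sum over all y of v_y) - i_d sum d_y`}
#' }
#' The SSCA power law lives in [value_signal()], so SSCA and SCA share the
#' same drift form.
#'
#' @param params An [ssm_params()] object.
#' @param v Value-signal vector (from [value_signal()]).
#' @param d Current decision-signal vector (nonnegative).
#' @return Numeric vector of deterministic increments, one per alternative.
#' @export
drift_increment <- function(params, v, d) {
  stopifnot(length(v) == length(d), all(d >= 0))
  m <- length(v)
  voth <- sum(v) - v
  doth <- sum(d) - d
  with(params, switch(
    params$model,
    RACE = b + g * v,
    NDD = b + g * (v - voth / (m - 1)),
    SNFI = b + g * (v - i_v * voth),
    DNFI = g * (b + v) / (s + sum(v)),
    CA = b + g * v - i_d * doth,
    SCA = b + g * (v - i_v * voth) - i_d * doth,
    SSCA = b + g * (v - i_v * voth) - i_d * doth,
    DCA = g * (b + v) / (s + sum(v)) - i_d * doth,
    stop("unknown model", call. = FALSE)
  ))
}

#' One rectified stochastic state update
#'
#' Applies the shared recurrence `d_x(t + dt) = max{0, d_x(t) + f_x + eps_x}`:
#' drift and noise are summed first, then the whole update is rectified at
#' zero (a threshold-linear activation; rectification is never applied to
#' the inputs separately).
#'
#' @param state List with elements `d` (decision-signal vector, nonnegative)
#'   and `t_ms` (elapsed time).
#' @param increment Deterministic increment vector (from
#'   [drift_increment()]).
#' @param noise_draw Noise vector, one i.i.d. `N(0, sigma^2)` draw per
#'   alternative.
#' @param dt_ms Time step in ms.
#' @return The updated state list.
#' @export
update_state <- function(state, increment, noise_draw, dt_ms = 10) {
  stopifnot(all(state$d >= 0),
            length(increment) == length(state$d),
            length(noise_draw) == length(state$d))
  list(d = pmax(0, state$d + increment + noise_draw),
       t_ms = state$t_ms + dt_ms)
}
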