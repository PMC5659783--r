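#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib valuessm, .registration = TRUE
#' @importFrom rlang .data
#' @importFrom stats coef glm lm optim pchisq pnorm pt quantile rnorm runif
#'   setNames t.test vcov plogis qlogis approx sd
#' @importFrom utils modifyList
NULL

# Registry of the eight accumulator models. `active` lists the free
# parameters of each model; `code` matches the enum in src/simulate.cpp.
model_registry <- function() {
  tibble::tibble(
    model = c("RACE", "NDD", "SNFI", "DNFI", "CA", "SCA", "DCA", "SSCA"),
    code = 0:7,
    df = c(3L, 3L, 4L, 4L, 4L, 5L, 5L, 6L),
    active = list(
      c("b", "g", "sigma"),
      c("b", "g", "sigma"),
      c("b", "g", "sigma", "i_v"),
      c("b", "g", "sigma", "s"),
      c("b", "g", "sigma", "i_d"),
      c("b", "g", "sigma", "i_v", "i_d"),
      c("b", "g", "sigma", "s", "i_d"),
      c("b", "g", "sigma", "i_v", "i_d", "a")
    )
  )
}

#' Model identifiers
#'
#' The eight accumulator models, in ascending order of complexity:
#' independent race (`RACE`), neural drift-diffusion (`NDD`), subtractive
#' and divisive normalization-or-feedforward-inhibition (`SNFI`, `DNFI`),
#' competing accumulator (`CA`), subtractive and divisive competing
#' accumulator (`SCA`, `DCA`), and the supralinear subtractive competing
#' accumulator (`SSCA`).
#'
#' @return Character vector of model names.
#' @export
ssm_models <- function() model_registry()$model

#' Free parameters of a model
#'
#' @param model Model identifier (see [ssm_models()]).
#' @return Character vector naming the model's free parameters.
#' @export
active_params <- function(model) {
  reg <- model_registry()
  i <- match(match.arg(toupper(model), reg$model), reg$model)
  reg$active[[i]]
}

#' Degrees of freedom of a model
#'
#' @inheritParams active_params
#' @return Integer count of free parameters.
#' @export
model_df <- function(model) length(active_params(model))

model_code <- function(model) {
  reg <- model_registry()
  reg$code[match(toupper(model), reg$model)]
}

#' Construct a model parameter set
#'
#' Bundles the free parameters of one of the eight accumulator models and
#' validates them against the model's parameter mask and constraints:
#' `b >= 0`, `g > 0`, `sigma >= 0`, `0 <= i_v <= 1`, `s > 0`,
#' `0 <= i_d <= 1`, `a >= 1`. Parameters that are not free under `model`
#' must be left `NULL`.
#'
#' Units: `b` is baseline input per 10-ms step (activation units), `g` is a
#' dimensionless input gain, `sigma` is the per-step noise standard
#' deviation, `i_v` and `i_d` are inhibition weights, `s` is the
#' semisaturation constant (value units), and `a` is the attentional
#' exponent.
#'
#' @param model Model identifier.
#' @param b Baseline input per step.
#' @param g Value-signal gain.
#' @param sigma Per-step noise standard deviation.
#' @param i_v Value-signal (input-dependent) inhibition weight.
#' @param s Semisaturation constant of the divisive transform.
#' @param i_d Decision-signal (state-dependent) inhibition weight.
#' @param a Supralinear attentional exponent.
#' @return An object of class `ssm_params`.
#' @examples
#' ssm_params("SCA", b = 1.195, g = 0.187, sigma = 2.665,
#'            i_v = 0.470, i_d = 0.0154)
#' @export
ssm_params <- function(model, b, g, sigma,
                       i_v = NULL, s = NULL, i_d = NULL, a = NULL) {
  model <- match.arg(toupper(model), ssm_models())
  given <- list(b = b, g = g, sigma = sigma, i_v = i_v, s = s,
                i_d = i_d, a = a)
  given <- given[!vapply(given, is.null, logical(1))]
  act <- active_params(model)
  extra <- setdiff(names(given), act)
  if (length(extra) > 0) {
    stop(sprintf("parameter(s) %s are not free under the %s model",
                 paste(extra, collapse = ", "), model), call. = FALSE)
  }
  missing <- setdiff(act, names(given))
  if (length(missing) > 0) {
    stop(sprintf("the %s model requires parameter(s) %s",
                 model, paste(missing, collapse = ", ")), call. = FALSE)
  }
  stopifnot(given$b >= 0, given$g > 0, given$sigma >= 0)
  if ("i_v" %in% act) stopifnot(given$i_v >= 0, given$i_v <= 1)
  if ("s" %in% act) stopifnot(given$s > 0)
  if ("i_d" %in% act) stopifnot(given$i_d >= 0, given$i_d <= 1)
  if ("a" %in% act) stopifnot(given$a >= 1)
  structure(c(list(model = model), given), class = "ssm_params")
}

#' @export
print.ssm_params <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "model")])
  cat(sprintf("<ssm_params> %s model (%d df)\n", x$model, model_df(x$model)))
  cat(paste(sprintf("  %-5s %.6g", names(vals), vals), collapse = "\n"), "\n")
  invisible(x)
}

# Full numeric vector (b, g, sigma, i_v, s, i_d, a) with zeros in inactive
# slots, for the C++ core.
param_vector <- function(params) {
  full <- c(b = 0, g = 0, sigma = 0, i_v = 0, s = 1, i_d = 0, a = 1)
  got <- unlist(params[setdiff(names(params), "model")])
  full[names(got)] <- got
  full
}

#' Published fitted parameter sets
#'
#' Parameter values previously fitted to a large binary food-choice
#' experiment (four linearly ranked values, threshold 100, 10-ms steps,
#' 150-ms predecision time), together with the training- and test-half
#' chi-square statistics achieved. These are the parameter sets under which
#' the published model-predicted regression signatures (see
#' [reference_model_rows()]) were generated, and are the package's default
#' inputs for [reproduce_model_rows()].
#'
#' @return A tibble with one row per model: parameter columns (`NA` where a
#'   parameter is not free for that model), `chi2_training`, `chi2_test`.
#' @export
reference_fits <- function() {
  tibble::tribble(
    ~model, ~b,    ~g,    ~sigma, ~i_v,  ~s,    ~i_d,   ~a,    ~chi2_training, ~chi2_test,
    "SSCA", 1.434, 0.085, 2.265,  0.465, NA,    0.0180, 1.373, 153.26,  186.84,
    "SCA",  1.195, 0.187, 2.665,  0.470, NA,    0.0154, NA,    189.50,  227.41,
    "DCA",  3.073, 5.117, 2.571,  NA,    13.80, 0.0174, NA,    240.03,  295.48,
    "CA",   1.219, 0.233, 1.933,  NA,    NA,    0.0252, NA,    278.85,  296.49,
    "SNFI", 0.614, 0.225, 3.968,  0.733, NA,    NA,     NA,    322.65,  354.44,
    "DNFI", 0.109, 2.212, 3.970,  NA,    1.697, NA,     NA,    422.12,  461.82,
    "NDD",  0.761, 0.185, 3.803,  NA,    NA,    NA,     NA,    437.77,  501.84,
    "RACE", 0.336, 0.233, 3.569,  NA,    NA,    NA,     NA,    1257.36, 1255.40
  )
}

#' Published fitted parameters for one model
#'
#' @inheritParams active_params
#' @return An [ssm_params()] object holding the published fit.
#' @export
reference_params <- function(model) {
  model <- match.arg(toupper(model), ssm_models())
  row <- dplyr::filter(reference_fits(), .data$model == !!model)
  vals <- as.list(row[active_params(model)])
  do.call(ssm_params, c(list(model = model), vals))
}

#' Write and read parameter sets as key-value text
#'
#' Serializes an [ssm_params()] object to a plain-text `key: value` file
#' (full double precision via "%.17g") and reads it back losslessly.
#'
#' @param params An `ssm_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns an `ssm_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ssm_params"))
  vals <- params[setdiff(names(params), "model")]
  lines <- c(
    sprintf("model: %s", params$model),
    vapply(names(vals), function(nm) sprintf("%s: %.17g", nm, vals[[nm]]), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]+:", "", lines))
  names(vals) <- trimws(keys)
  model <- vals[["model"]]
  nums <- lapply(vals[setdiff(names(vals), "model")], as.numeric)
  do.call(ssm_params, c(list(model = model), nums))
}
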