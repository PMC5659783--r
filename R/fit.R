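# Bounded <-> unbounded reparameterization used by the simplex search:
# log for positive parameters, logit for [0, 1] weights, shifted log for
# the attentional exponent (a >= 1).
transform_params <- function(values, names) {
  vapply(seq_along(values), function(i) {
    switch(names[i],
           b = , g = , sigma = , s = log(values[i]),
           i_v = , i_d = qlogis(pmin(pmax(values[i], 1e-8), 1 - 1e-8)),
           a = log(max(values[i] - 1, 1e-8)))
  }, numeric(1))
}

untransform_params <- function(theta, names) {
  out <- vapply(seq_along(theta), function(i) {
    switch(names[i],
           b = , g = , sigma = , s = exp(theta[i]),
           i_v = , i_d = plogis(theta[i]),
           a = 1 + exp(theta[i]))
  }, numeric(1))
  setNames(out, names)
}

# Random starting values on the natural scale: baseline, noise, and
# competition parameters are drawn log-uniformly (or uniformly for the
# bounded weights) over generously wide ranges, and the gain is then
# moment-matched so that the noiseless first passage of the mean input
# roughly reproduces the observed median RT (`calib`). This anchors every
# candidate at a sane time scale and leaves the simplex to resolve the
# competition/attention trade-offs.
random_start <- function(names, model, calib) {
  draw <- function(nm) {
    switch(nm,
           b = exp(runif(1, log(0.05), log(3))),
           g = exp(runif(1, log(0.02), log(5))),
           sigma = exp(runif(1, log(0.5), log(6))),
           i_v = runif(1, 0.05, 0.95),
           s = exp(runif(1, log(0.3), log(30))),
           i_d = exp(runif(1, log(0.002), log(0.08))),
           a = 1 + exp(runif(1, log(0.05), log(0.8))))
  }
  st <- setNames(vapply(names, draw, numeric(1)), names)
  if (!is.null(calib)) st["g"] <- calibrate_gain(st, model, calib)
  st
}

# Observed summaries distilled for start calibration.
make_calib <- function(observed, config) {
  pairs <- dplyr::distinct(observed, .data$v_lo, .data$v_hi)
  unequal <- pairs$v_lo != pairs$v_hi
  list(
    rt50 = stats::median(observed$q50, na.rm = TRUE),
    onset_steps = round(config$t0_ms / config$dt_ms),
    t0_ms = config$t0_ms, dt_ms = config$dt_ms,
    threshold = config$threshold,
    v_hi = if (any(unequal)) pairs$v_hi[unequal] else pairs$v_hi,
    v_lo = if (any(unequal)) pairs$v_lo[unequal] else pairs$v_lo)
}

clip_start <- function(st, names) {
  st <- st[names]
  for (nm in names) {
    st[nm] <- switch(nm,
                     b = max(st[[nm]], 1e-4),
                     g = min(max(st[[nm]], 1e-3), 50),
                     sigma = max(st[[nm]], 0.05),
                     s = max(st[[nm]], 1e-3),
                     i_v = , i_d = min(max(st[[nm]], 1e-4), 0.9999),
                     a = max(st[[nm]], 1 + 1e-6))
  }
  st
}

# Profile stage for the hybrid models: hold each structural grid point
# (competition weights, attentional exponent) fixed, profile the shared,
# well-conditioned trio (b, g, sigma) with a short low-fidelity simplex,
# and return the best few grid points - refined over all parameters by the
# main search - as screening candidates.
profile_starts <- function(model, nms, pairs, config, calib, objective_for,
                           seed, n_top = 3) {
  grid <- structural_grid(model)
  prof_design <- tibble::tibble(
    v_left = rep(pairs$v_lo, each = 500),
    v_right = rep(pairs$v_hi, each = 500))
  prof_obj <- objective_for(prof_design)
  prof_seed <- (seed * 1000L + 555L) %% .Machine$integer.max
  shared <- match(c("b", "g", "sigma"), nms)
  results <- vector("list", nrow(grid))
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    st <- setNames(numeric(length(nms)), nms)
    if (!"b" %in% names(grid)) st[["b"]] <- 1
    st[["sigma"]] <- 2.5
    st[names(grid)] <- unlist(grid[i, ])
    st[["g"]] <- calibrate_gain(st, model, calib)
    theta_full <- transform_params(clip_start(st, nms), nms)
    o <- optim(rep(0, 3), function(delta, crn_seed) {
      th <- theta_full
      th[shared] <- th[shared] + delta
      prof_obj(th, crn_seed)
    }, crn_seed = prof_seed, method = "Nelder-Mead",
    control = list(maxit = 60))
    theta_full[shared] <- theta_full[shared] + o$par
    results[[i]] <- untransform_params(theta_full, nms)
    scores[i] <- o$value
  }
  results[order(scores)[seq_len(min(n_top, length(scores)))]]
}

# Structural-parameter grid for the profile stage of the hybrid models:
# the competition weights (and attentional exponent) span their plausible
# ranges coarsely; the shared trio (b, g, sigma) is profiled out at each
# grid point.
structural_grid <- function(model) {
  # For the divisive models the baseline is normalized by the
  # semisaturation and spans orders of magnitude, so it is gridded rather
  # than profiled from a single default.
  switch(model,
         SNFI = tidyr::expand_grid(i_v = c(0.1, 0.3, 0.5, 0.7, 0.9)),
         DNFI = tidyr::expand_grid(s = c(0.5, 1.5, 5, 15),
                                   b = c(0.1, 1, 3)),
         CA = tidyr::expand_grid(i_d = c(0.003, 0.008, 0.02, 0.05)),
         SCA = tidyr::expand_grid(i_v = c(0.15, 0.35, 0.55, 0.75),
                                  i_d = c(0.005, 0.015, 0.035)),
         DCA = tidyr::expand_grid(s = c(1.5, 5, 15),
                                  i_d = c(0.005, 0.015, 0.035),
                                  b = c(0.1, 1, 3)),
         SSCA = tidyr::expand_grid(i_v = c(0.15, 0.35, 0.55, 0.75),
                                   i_d = c(0.005, 0.015, 0.035),
                                   a = c(1.15, 1.4)),
         NULL)
}

# Solve the gain so that the noiseless first passage of the mean unequal
# input pair lands at the observed median RT. The deterministic recurrence
# is iterated exactly (rectification, input- and state-dependent
# competition, the attentional power law included), and the gain is found
# by bisection on its log, exploiting that the crossing time decreases
# monotonically in the gain.
calibrate_gain <- function(st, model, calib) {
  vbar <- c(mean(calib$v_hi), mean(calib$v_lo))
  onset <- calib$onset_steps
  D <- calib$threshold
  target <- calib$rt50
  max_steps <- onset + 4L * max(5L, round((target - calib$t0_ms) / calib$dt_ms))
  t_cross <- function(g) {
    vals <- as.list(st[setdiff(names(st), "g")])
    p <- tryCatch(
      do.call(ssm_params, c(list(model = model, g = g), vals)),
      error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    v_post <- value_signal(vbar, calib$t0_ms, p)
    d <- c(0, 0)
    for (k in seq_len(max_steps)) {
      v <- if (k - 1 >= onset) v_post else c(0, 0)
      d <- pmax(0, d + drift_increment(p, v, d))
      if (max(d) >= D) return(k * calib$dt_ms)
    }
    Inf
  }
  lo <- log(1e-3)
  hi <- log(50)
  if (!is.finite(t_cross(exp(hi))) || t_cross(exp(hi)) > target) {
    return(exp(hi))
  }
  if (t_cross(exp(lo)) <= target) return(exp(lo))
  for (i in seq_len(30)) {
    mid <- (lo + hi) / 2
    tc <- t_cross(exp(mid))
    if (is.finite(tc) && tc <= target) hi <- mid else lo <- mid
  }
  exp(hi)
}

#' Fit an accumulator model by Monte-Carlo chi-square minimization
#'
#' Minimizes the quantile-based chi-square objective
#' ([chi2_statistic()]) over the model's free parameters using the
#' Nelder-Mead simplex with randomized restarts. Each objective evaluation
#' simulates `trials_per_vector` trials per input-value pair; common random
#' numbers are used within a restart (the RNG is reseeded identically
#' before every simulation) so the search surface is deterministic given
#' the restart seed. Bound constraints are enforced by reparameterization
#' (log for positive parameters, logit for inhibition weights in
#' `[0, 1]`, shifted log for the exponent `a >= 1`).
#'
#' @param model Model identifier (see [ssm_models()]).
#' @param observed An [quantile_table()] summary with at least two pairs.
#' @param config An [ssm_config()] object.
#' @param trials_per_vector Simulated trials per input vector per
#'   objective evaluation.
#' @param restarts Number of random restarts.
#' @param maxit Simplex iterations per restart.
#' @param n_screen Randomized seeding: candidate starting points drawn and
#'   evaluated once per restart; the simplex starts from the best.
#' @param init Optional list of named parameter vectors (natural scale)
#'   added to every restart's screening pool.
#' @param warm_start For every model with structural parameters beyond
#'   the shared trio, precede the random restarts with a profile stage: a
#'   coarse grid over the structural parameters (competition weights,
#'   semisaturation, attentional exponent) with the well-conditioned trio
#'   (`b`, `g`, `sigma`) profiled out by a short low-fidelity simplex at
#'   each grid point; the best grid points seed every restart's screening
#'   pool. Defaults to `TRUE` except for RACE and NDD, which have no
#'   structural parameters.
#' @param seed Master seed; restart seeds and common-random-number seeds
#'   derive from it.
#' @return An object of class `ssm_fit`: fitted [ssm_params()], `chi2`,
#'   `df`, `n_cells` (bin cells entering the objective), `aicc`, `bic`, a
#'   restart log, and the seed. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_model <- function(model, observed, config = ssm_config(),
                      trials_per_vector = 2000, restarts = 20,
                      maxit = 400, n_screen = 20, init = NULL,
                      warm_start = !model %in% c("RACE", "NDD"),
                      seed = 1) {
  model <- match.arg(toupper(model), ssm_models())
  stopifnot(inherits(observed, "ssm_quantiles"))
  pairs <- dplyr::distinct(observed, .data$v_lo, .data$v_hi)
  if (nrow(pairs) < 2) stop("need at least two input vectors", call. = FALSE)
  design <- tibble::tibble(
    v_left = rep(pairs$v_lo, each = trials_per_vector),
    v_right = rep(pairs$v_hi, each = trials_per_vector))
  nms <- active_params(model)
  calib <- make_calib(observed, config)
  make_params <- function(vals) {
    do.call(ssm_params, c(list(model = model), as.list(vals)))
  }
  objective_for <- function(des) {
    function(theta, crn_seed) {
      vals <- untransform_params(theta, nms)
      if (any(!is.finite(vals))) return(1e12)
      p <- make_params(vals)
      sim <- simulate_dataset(p, des, config, seed = crn_seed)
      if (mean(sim$crossed) < 0.05) return(1e10)
      as.numeric(chi2_statistic(observed, sim))
    }
  }
  objective <- objective_for(design)
  if (isTRUE(warm_start) && !is.null(structural_grid(model))) {
    init <- c(init, profile_starts(model, nms, pairs, config, calib,
                                   objective_for, seed))
  }
  init <- lapply(init, clip_start, names = nms)
  # Restarts are compared on an out-of-sample re-evaluation under
  # validation seeds independent of every restart's common-random-number
  # stream: a simplex can exploit its own fixed noise realization
  # (apparent chi-square far below the expected one), and in-sample values
  # would systematically select those solutions.
  val_seeds <- (seed * 1000L + 777L + 0:1) %% .Machine$integer.max
  validate <- function(theta) {
    mean(vapply(val_seeds, function(s) objective(theta, s), numeric(1)))
  }
  log_rows <- vector("list", restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    crn_seed <- (seed * 1000L + r) %% .Machine$integer.max
    set.seed(crn_seed)
    starts <- c(init,
                replicate(max(1L, n_screen), random_start(nms, model, calib),
                          simplify = FALSE))
    screened <- vapply(starts, function(st) {
      objective(transform_params(st, nms), crn_seed)
    }, numeric(1))
    theta0 <- transform_params(starts[[which.min(screened)]], nms)
    # Several simplex rounds from the running incumbent. Each round
    # optimizes displacements from the incumbent so its initial steps are a
    # uniform 0.1 on the transformed scale (optim would otherwise size them
    # by coordinate magnitude, collapsing near zero), and each round uses a
    # fresh common-random-number stream: a simplex left on one stream
    # learns to exploit that noise realization, and its spurious minima do
    # not survive the stream change, whereas real structure does.
    opt <- tryCatch({
      inc <- theta0
      conv <- 1L
      for (j in seq_len(3)) {
        round_seed <- (crn_seed + 13L * j) %% .Machine$integer.max
        oj <- optim(rep(0, length(inc)),
                    function(delta, crn_seed) objective(inc + delta, crn_seed),
                    crn_seed = round_seed,
                    method = "Nelder-Mead", control = list(maxit = maxit))
        inc <- inc + oj$par
        conv <- oj$convergence
      }
      list(par = inc, value = oj$value, convergence = conv)
    }, error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) {
      log_rows[[r]] <- tibble::tibble(restart = r, chi2 = NA_real_,
                                      chi2_val = NA_real_, converged = FALSE)
      next
    }
    val <- validate(opt$par)
    log_rows[[r]] <- tibble::tibble(restart = r, chi2 = opt$value,
                                    chi2_val = val,
                                    converged = opt$convergence == 0)
    if (is.null(best) || val < best$value) {
      best <- list(value = val, theta = opt$par, crn_seed = crn_seed)
    }
  }
  if (is.null(best)) {
    stop("objective was non-finite at every restart; see the restart log",
         call. = FALSE)
  }
  fitted <- make_params(untransform_params(best$theta, nms))
  # Reported objective value comes from a fresh validation simulation, not
  # from the stream the simplex was allowed to adapt to.
  sim <- simulate_dataset(fitted, design, config, seed = val_seeds[1])
  chi2 <- chi2_statistic(observed, sim)
  k <- length(nms)
  n_cells <- attr(chi2, "n_bins")
  ic <- information_criteria(as.numeric(chi2), k, n_cells)
  structure(list(params = fitted, model = model, chi2 = as.numeric(chi2),
                 df = k, n_cells = n_cells, aicc = ic[["aicc"]],
                 bic = ic[["bic"]],
                 restart_log = dplyr::bind_rows(log_rows),
                 seed = seed, crn_seed = best$crn_seed,
                 trials_per_vector = trials_per_vector, config = config),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("<ssm_fit> %s model: chi2 = %.2f (df %d, %d bin cells)\n",
              x$model, x$chi2, x$df, x$n_cells))
  cat(sprintf("  AICc = %.2f, BIC = %.2f\n", x$aicc, x$bic))
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy ssm_fit
#' @export
tidy.ssm_fit <- function(x, ...) {
  nms <- active_params(x$model)
  tibble::tibble(model = x$model, parameter = nms,
                 estimate = unlist(x$params[nms], use.names = FALSE))
}

#' @method glance ssm_fit
#' @export
glance.ssm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, chi2 = x$chi2, df = x$df,
                 n_cells = x$n_cells, aicc = x$aicc, bic = x$bic)
}

#' Penalized model-comparison criteria
#'
#' Treating the chi-square objective as a deviance proxy:
#' `AICc = chi2 + 2k + 2k(k + 1)/(n - k - 1)` and
#' `BIC = chi2 + k log(n)`, with `k` free parameters and `n` summary
#' observations (bin cells).
#'
#' @param chi2 Objective value.
#' @param k Number of free parameters.
#' @param n_cells Number of summary observations.
#' @return Named numeric vector with elements `aicc` and `bic`.
#' @export
information_criteria <- function(chi2, k, n_cells) {
  stopifnot(chi2 >= 0, k >= 0)
  if (n_cells <= k + 1) {
    stop("AICc undefined: n_cells must exceed k + 1", call. = FALSE)
  }
  c(aicc = chi2 + 2 * k + 2 * k * (k + 1) / (n_cells - k - 1),
    bic = chi2 + k * log(n_cells))
}

# Direct nesting edges; nesting_pairs() closes them transitively.
nesting_edges <- function() {
  list(c("RACE", "SNFI"), c("RACE", "CA"), c("NDD", "SNFI"),
       c("SNFI", "SCA"), c("CA", "SCA"), c("CA", "DCA"),
       c("DNFI", "DCA"), c("SCA", "SSCA"))
}

is_nested_in <- function(nested, full) {
  edges <- nesting_edges()
  reach <- nested
  repeat {
    nxt <- unique(unlist(lapply(edges, function(e) {
      if (e[1] %in% reach) e[2] else NULL
    })))
    if (all(nxt %in% reach)) break
    reach <- union(reach, nxt)
  }
  full %in% setdiff(reach, nested)
}

#' Likelihood-ratio test between nested fits
#'
#' Refers the difference in chi-square objectives between a nested and a
#' full model to a chi-square law with degrees of freedom equal to the
#' difference in free parameters. Negative differences (Monte-Carlo noise)
#' are clamped to zero with a warning. Non-nested pairs are rejected; use
#' the information criteria instead.
#'
#' @param fit_nested,fit_full [fit_model()] results (or lists with
#'   elements `model`, `chi2`, `df`).
#' @return A tibble with `statistic`, `delta_df`, `p_value`.
#' @export
lr_test <- function(fit_nested, fit_full) {
  if (!is_nested_in(fit_nested$model, fit_full$model)) {
    stop(sprintf(
      "%s is not nested in %s; compare with information criteria instead",
      fit_nested$model, fit_full$model), call. = FALSE)
  }
  stat <- fit_nested$chi2 - fit_full$chi2
  if (stat < 0) {
    warning("nested model fit better than the full model ",
            "(Monte-Carlo noise); statistic clamped to 0")
    stat <- 0
  }
  ddf <- fit_full$df - fit_nested$df
  tibble::tibble(statistic = stat, delta_df = ddf,
                 p_value = pchisq(stat, ddf, lower.tail = FALSE))
}
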