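test_that("summaries report choice frequencies and interpolated quantiles", {
  tab <- quantile_table(toy_dataset())
  cell <- dplyr::filter(tab, v_lo == 1, v_hi == 3)
  expect_equal(cell$freq[cell$category == "hi"], 0.6)
  expect_equal(cell$freq[cell$category == "lo"], 0.4)
  # 10 RTs at 400..1300 in 100-ms steps: median 850 under linear
  # interpolation between order statistics
  ten <- toy_dataset() |>
    dplyr::filter(v_left == 3, choice == "L") |>
    dplyr::slice(1:10)
  expect_equal(quantile_table(ten)$q50, 850)
  # frequencies sum to one within each pair
  sums <- tab |>
    dplyr::group_by(v_lo, v_hi) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))
  # quantiles are non-decreasing within a row
  qs <- as.matrix(tab[, c("q10", "q30", "q50", "q70", "q90")])
  expect_true(all(t(apply(qs, 1, diff)) >= 0))
})

test_that("fast contaminants are excluded from all summaries", {
  d <- toy_dataset()
  d$rt_ms[1] <- 250
  tab <- quantile_table(d)
  expect_equal(attr(tab, "n_total"), nrow(d) - 1)
  expect_true(all(tab$rt_min >= 300))
})

test_that("small cells contribute frequency only", {
  d <- toy_dataset()
  # leave 4 "lo" choices in the (1,3) cell
  d <- d[-(13:16), ]
  tab <- quantile_table(d)
  lo <- dplyr::filter(tab, v_lo == 1, v_hi == 3, category == "lo")
  expect_true(is.na(lo$q50))
  expect_equal(lo$n, 4L)
})

test_that("the chi-square objective vanishes for an identical distribution", {
  d <- round_dataset()
  tab <- quantile_table(d)
  expect_lt(abs(chi2_statistic(tab, d)), 1e-9)
})

test_that("the two-bin hand-worked contribution is exact", {
  # (30-50)^2/50 + (70-50)^2/50 = 16, hand-checked
  expect_equal(chi2_bins(c(0.3, 0.7), c(0.5, 0.5), 100), 16)
})

test_that("chi-square is invariant to left/right relabeling within cells", {
  d <- round_dataset()
  tab <- quantile_table(d)
  flipped <- d |>
    dplyr::mutate(v_left = d$v_right, v_right = d$v_left,
                  choice = ifelse(d$choice == "L", "R", "L"))
  expect_equal(as.numeric(chi2_statistic(tab, flipped)),
               as.numeric(chi2_statistic(tab, d)))
})

test_that("chi-square decomposes additively over input vectors", {
  p <- reference_params("SCA")
  obs_d <- simulate_dataset(p, design_grid(1:3, 400), seed = 1)
  pred <- simulate_dataset(p, design_grid(1:3, 400), seed = 2)
  total <- as.numeric(chi2_statistic(quantile_table(obs_d), pred))
  parts <- vapply(list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3)),
                  function(pr) {
    sub <- dplyr::filter(obs_d, pmin(v_left, v_right) == pr[1],
                         pmax(v_left, v_right) == pr[2])
    tab1 <- quantile_table(sub)
    # per-pair weight must match the full table's common n_eff
    attr(tab1, "n_total") <- attr(quantile_table(obs_d), "n_total")
    attr(tab1, "n_pairs") <- attr(quantile_table(obs_d), "n_pairs")
    as.numeric(chi2_statistic(tab1, pred))
  }, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-10)
})

test_that("summaries are invariant to record order", {
  d <- round_dataset()
  shuffled <- d[sample.int(nrow(d)), ]
  expect_equal(tibble::as_tibble(quantile_table(shuffled)),
               tibble::as_tibble(quantile_table(d)))
})

test_that("information criteria follow the stated penalties", {
  ic <- information_criteria(153.26, 6, 120)
  # hand-checked: 153.26 + 12 + 84/113 and 153.26 + 6 * log(120)
  expect_equal(ic[["aicc"]], 166.0033628318584, tolerance = 1e-10)
  expect_equal(ic[["bic"]], 181.9849504566923, tolerance = 1e-10)
  expect_equal(unname(information_criteria(42, 0, 10)), c(42, 42))
  expect_error(information_criteria(10, 6, 7), "n_cells")
  # BIC penalty exceeds AICc penalty for large n
  ic2 <- information_criteria(0, 4, 200)
  expect_gt(ic2[["bic"]], ic2[["aicc"]])
})

test_that("likelihood-ratio tests respect the nesting lattice", {
  f_sca <- list(model = "SCA", chi2 = 189.50, df = 5L)
  f_ssca <- list(model = "SSCA", chi2 = 153.26, df = 6L)
  out <- lr_test(f_sca, f_ssca)
  expect_equal(out$delta_df, 1L)
  expect_equal(out$statistic, 189.50 - 153.26)
  # identical fits: statistic 0, p = 1
  same <- lr_test(list(model = "SCA", chi2 = 100, df = 5L),
                  list(model = "SSCA", chi2 = 100, df = 6L))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # the canonical chi-square quantile
  p05 <- lr_test(list(model = "SCA", chi2 = 103.84, df = 5L),
                 list(model = "SSCA", chi2 = 100, df = 6L))
  expect_equal(p05$p_value, 0.05, tolerance = 1e-2)
  # Monte-Carlo inversions clamp to zero with a warning
  expect_warning(
    inv <- lr_test(list(model = "SCA", chi2 = 99, df = 5L),
                   list(model = "SSCA", chi2 = 100, df = 6L)))
  expect_equal(inv$statistic, 0)
  # non-nested pairs are refused
  expect_error(lr_test(list(model = "NDD", chi2 = 1, df = 3L),
                       list(model = "CA", chi2 = 1, df = 4L)),
               "not nested")
})

test_that("the parity split is deterministic, disjoint, and exhaustive", {
  d <- tibble::tibble(subject = rep(1:2, each = 10), trial = rep(1:10, 2))
  sp <- parity_split(d)
  expect_equal(nrow(sp$training) + nrow(sp$test), nrow(d))
  expect_equal(nrow(dplyr::inner_join(sp$training, sp$test,
                                      by = c("subject", "trial"))), 0)
  # odd subject contributes odd trials to training
  expect_true(all(sp$training$trial[sp$training$subject == 1] %% 2 == 1))
  # even subject contributes even trials
  expect_true(all(sp$training$trial[sp$training$subject == 2] %% 2 == 0))
  # idempotent
  sp2 <- parity_split(sp$training)
  expect_equal(nrow(sp2$training), nrow(sp$training))
  expect_error(parity_split(tibble::tibble(x = 1)), "subject")
})

test_that("benchmark predictors behave as designed", {
  d <- round_dataset()
  tab <- quantile_table(d)
  sat <- saturated_predictor(tab)
  expect_identical(as.numeric(chi2_statistic(tab, sat)), 0)
  nul <- null_predictor(tab)
  # null choice frequency is common to all unequal cells by construction
  expect_equal(valuessm:::predictor_freq(nul, list(category = "hi")), 0.5)
  # null RT density integrates to one over its support
  rng <- nul$rt_range
  expect_equal(diff(valuessm:::predictor_cdf(nul, NULL, rng)), 1)
  expect_gt(as.numeric(chi2_statistic(tab, nul)), 0)
})

test_that("fitting recovers generating parameters of the race model", {
  p <- reference_params("RACE")
  dat <- simulate_dataset(p, design_grid(1:4, 1500), seed = 15)
  obs <- quantile_table(dat)
  fit <- fit_model("RACE", obs, trials_per_vector = 800, restarts = 2,
                   maxit = 150, n_screen = 30, seed = 8)
  est <- unlist(fit$params[c("b", "g", "sigma")])
  truth <- unlist(p[c("b", "g", "sigma")])
  expect_lt(max(abs(est / truth - 1)), 0.15)
  expect_equal(fit$df, 3L)
  expect_gte(fit$chi2, 0)
  # the generating parameters beat a 50% perturbation on the same objective
  design <- design_grid(1:4, 800)
  ev <- function(pp) {
    sim <- simulate_dataset(pp, design, seed = fit$crn_seed)
    as.numeric(chi2_statistic(obs, sim))
  }
  worse <- ssm_params("RACE", b = 0.336 * 1.5, g = 0.233 * 1.5,
                      sigma = 3.569 * 1.5)
  expect_lt(ev(p), ev(worse))
})
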