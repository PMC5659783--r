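test_that("trials are classified by the value of the chosen option", {
  d <- tibble::tibble(
    subject = 1L, trial = 1:4,
    v_left = c(3L, 2L, 1L, 3L), v_right = c(1L, 2L, 4L, 1L),
    choice = c("L", "R", "L", "R"),
    rt_ms = c(500, 600, 700, 250), crossed = TRUE)
  cls <- classify_trials(d)
  expect_equal(cls$category, c("correct", "indifferent", "incorrect"))
  # the 250-ms contaminant is dropped
  expect_equal(nrow(cls), 3)
})

test_that("value normalization maps the scale onto the unit interval", {
  d <- tibble::tibble(v_left = 1:4, v_right = c(4L, 3L, 2L, 1L))
  n1 <- normalize_values(d, levels = 1:4)
  expect_equal(n1$v_left, c(0, 1 / 3, 2 / 3, 1))
  # an 11-level scale puts its midpoint at one half
  d2 <- tibble::tibble(v_left = 6, v_right = 1)
  expect_equal(normalize_values(d2, levels = 1:11)$v_left, 0.5)
  # idempotent on normalized data
  expect_equal(normalize_values(n1)$v_left, n1$v_left)
  expect_error(normalize_values(d, levels = 2), "two distinct")
})

test_that("complementary parameterizations are exact linear recombinations", {
  set.seed(21)
  p <- reference_params("SSCA")
  sim <- simulate_dataset(p, design_grid(1:4, 500), seed = 21)
  cls <- normalize_values(classify_trials(sim), levels = 1:4)
  rt <- fit_rt(cls, "correct")
  gl <- dplyr::filter(rt, parameterization == "greater+lesser")
  ds <- dplyr::filter(rt, parameterization == "difference+sum")
  bg <- gl$estimate[gl$term == "greater"]
  bl <- gl$estimate[gl$term == "lesser"]
  expect_equal(ds$estimate[ds$term == "difference"], (bg - bl) / 2,
               tolerance = 1e-10)
  expect_equal(ds$estimate[ds$term == "sum"], (bg + bl) / 2,
               tolerance = 1e-10)
  # the intercept is shared between the two parameterizations
  expect_equal(gl$estimate[gl$term == "constant"],
               ds$estimate[ds$term == "constant"], tolerance = 1e-10)
})

test_that("a pure greater-value effect splits evenly into difference and sum", {
  set.seed(31)
  n <- 4000
  g <- runif(n); l <- runif(n) * g
  y <- 1.2 - 0.4 * g + rnorm(n, 0, 0.05)
  d <- tibble::tibble(
    subject = 1L, trial = seq_len(n),
    v_left = pmax(g, l + 1e-6), v_right = pmin(g, l),
    choice = "L", rt_ms = y * 1000, crossed = TRUE)
  cls <- classify_trials(d, min_rt_ms = 0)
  rt <- fit_rt(cls, "correct")
  ds <- dplyr::filter(rt, parameterization == "difference+sum")
  expect_equal(ds$estimate[ds$term == "difference"], -0.2, tolerance = 0.02)
  expect_equal(ds$estimate[ds$term == "sum"], -0.2, tolerance = 0.02)
})

test_that("synthetic logistic data are recovered within two standard errors", {
  set.seed(41)
  n <- 6000
  g <- sample(c(1 / 3, 2 / 3, 1), n, replace = TRUE)
  l <- vapply(g, function(x) sample(seq(0, x - 1 / 3, by = 1 / 3), 1),
              numeric(1))
  eta <- -0.3 + 3.2 * g - 2.9 * l
  correct <- rbinom(n, 1, plogis(eta))
  d <- tibble::tibble(
    subject = 1L, trial = seq_len(n),
    v_left = g, v_right = l,
    choice = ifelse(correct == 1, "L", "R"),
    rt_ms = 800, crossed = TRUE)
  cls <- classify_trials(d, min_rt_ms = 0)
  acc <- fit_accuracy(cls)
  gl <- dplyr::filter(acc, parameterization == "greater+lesser")
  expect_lt(abs(gl$estimate[gl$term == "greater"] - 3.2) /
              gl$se[gl$term == "greater"], 2)
  expect_lt(abs(gl$estimate[gl$term == "lesser"] + 2.9) /
              gl$se[gl$term == "lesser"], 2)
})

test_that("value-independent choices give null coefficients", {
  set.seed(51)
  n <- 3000
  d <- tibble::tibble(
    subject = 1L, trial = seq_len(n),
    v_left = sample(1:4, n, TRUE), v_right = sample(1:4, n, TRUE),
    choice = sample(c("L", "R"), n, TRUE),
    rt_ms = 700 + 100 * rnorm(n)^2, crossed = TRUE) |>
    dplyr::filter(v_left != v_right)
  cls <- normalize_values(classify_trials(d, min_rt_ms = 0), levels = 1:4)
  acc <- fit_accuracy(cls)
  gl <- dplyr::filter(acc, parameterization == "greater+lesser",
                      term != "constant")
  expect_true(all(abs(gl$estimate) < 3 * gl$se))
})

test_that("constant RT yields zero normalized coefficients", {
  d <- tibble::tibble(
    subject = 1L, trial = 1:200,
    v_left = rep(c(2L, 3L, 4L, 4L), 50), v_right = rep(c(1L, 2L, 1L, 3L), 50),
    choice = "L", rt_ms = 900, crossed = TRUE)
  cls <- normalize_values(classify_trials(d), levels = 1:4)
  # a perfectly constant outcome makes summary.lm grumble; the zero
  # coefficients are still exactly what the normalization should return
  rt <- suppressWarnings(fit_rt(cls, "correct"))
  nonconst <- dplyr::filter(rt, term != "constant")
  expect_equal(nonconst$normalized, rep(0, nrow(nonconst)), tolerance = 1e-10)
  expect_equal(rt$estimate[rt$term == "constant"][1], 0.9)
})

test_that("absolute-magnitude contrasts match the hand-worked value", {
  out <- abs_contrast(3.517, 0.121, -3.038, 0.124)
  expect_equal(out$m, 0.479, tolerance = 1e-12)
  expect_lt(out$p_value, 0.05)
  expect_equal(abs_contrast(2, 0.1, -2, 0.1)$m, 0)
})

test_that("category RT comparisons use a two-tailed Welch test", {
  d <- tibble::tibble(
    subject = 1L, trial = 1:60,
    v_left = rep(c(3L, 2L), 30), v_right = rep(c(1L, 3L), 30),
    choice = "L", crossed = TRUE,
    rt_ms = rep(c(800, 800), 30) + rep(c(0, 50), 30) + rep(1:30, each = 2))
  cls <- classify_trials(d)
  out <- category_rt_test(cls, "incorrect", "correct")
  expect_equal(out$mean_diff_ms, 50)
  same <- category_rt_test(cls, "correct", "correct")
  expect_equal(same$mean_diff_ms, 0)
})

test_that("meta-aggregation weights tables by trial count", {
  t1 <- new_reg <- tibble::tibble(
    outcome = "rt_correct", parameterization = "difference+sum",
    term = c("constant", "sum"), estimate = c(1, 2), se = 0.1,
    statistic = 1, p_value = 0.5, normalized = c(1, 2),
    se_normalized = 0.1, n = 1000L)
  t2 <- dplyr::mutate(t1, estimate = c(1, 4), normalized = c(1, 4),
                      n = 3000L)
  cls1 <- structure(t1, class = c("ssm_regression", class(t1)))
  cls2 <- structure(t2, class = c("ssm_regression", class(t2)))
  agg <- meta_aggregate(list(cls1, cls2))
  expect_equal(agg$estimate[agg$term == "sum"], 3.5)
  expect_equal(agg$n[1], 4000L)
  # permutation invariance
  agg2 <- meta_aggregate(list(cls2, cls1))
  expect_equal(agg$estimate, agg2$estimate)
  expect_equal(agg$se, agg2$se)
  # a single table passes through unchanged
  expect_identical(meta_aggregate(list(cls1)), cls1)
})
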