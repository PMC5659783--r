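test_that("a noiseless trial crosses at the first post-onset step", {
  p <- ssm_params("RACE", b = 0, g = 1, sigma = 0)
  set.seed(1)
  tr <- simulate_trial(p, c(100, 50))
  expect_equal(tr$choice, 1L)
  expect_equal(tr$rt_ms, 160)
  expect_true(tr$crossed)
})

test_that("noiseless RTs match the step-count closed form", {
  # b = 2 per step for 15 predecision steps -> d = 30 at onset; thereafter
  # drift 2 + 1 * 4 = 6 per step, so ceiling((100 - 30) / 6) = 12 more
  # steps: RT = 150 + 120 ms. Oracle: hand arithmetic above.
  p <- ssm_params("RACE", b = 2, g = 1, sigma = 0)
  d <- simulate_dataset(p, design_grid(4:4, 10), seed = 1)
  expect_true(all(d$rt_ms == 270))
  expect_true(all(d$crossed))
})

test_that("R reference path and compiled path agree exactly", {
  for (m in c("RACE", "DNFI", "SSCA")) {
    p <- reference_params(m)
    for (v in list(c(4, 1), c(2, 2))) {
      set.seed(2024)
      a <- simulate_trial(p, v)
      set.seed(2024)
      b <- simulate_dataset(p, tibble::tibble(v_left = v[1], v_right = v[2]))
      expect_identical(a$rt_ms, b$rt_ms, info = m)
      expect_identical(a$crossed, b$crossed, info = m)
      if (a$crossed) {
        expect_identical(c("L", "R")[a$choice], b$choice, info = m)
      }
    }
  }
})

test_that("simulation is reproducible given a seed", {
  p <- reference_params("SCA")
  d1 <- simulate_dataset(p, design_grid(1:4, 20), seed = 7)
  d2 <- simulate_dataset(p, design_grid(1:4, 20), seed = 7)
  expect_identical_datasets(d1, d2)
})

test_that("symmetric values yield unbiased choices", {
  p <- reference_params("SCA")
  d <- simulate_dataset(p, tibble::tibble(v_left = rep(2, 4000),
                                          v_right = rep(2, 4000)), seed = 3)
  ph <- mean(d$choice == "L", na.rm = TRUE)
  expect_gt(ph, 0.5 - 3 * sqrt(0.25 / 4000))
  expect_lt(ph, 0.5 + 3 * sqrt(0.25 / 4000))
})

test_that("nesting identities hold exactly under a shared noise stream", {
  base <- list(b = 0.7, g = 0.2, sigma = 2.5)
  design <- design_grid(1:4, 30)
  pairs <- list(
    list(do.call(ssm_params, c(list("SNFI", i_v = 1), base)),
         do.call(ssm_params, c(list("NDD"), base))),
    list(do.call(ssm_params, c(list("SNFI", i_v = 0), base)),
         do.call(ssm_params, c(list("RACE"), base))),
    list(do.call(ssm_params, c(list("CA", i_d = 0), base)),
         do.call(ssm_params, c(list("RACE"), base))),
    list(do.call(ssm_params, c(list("SCA", i_v = 0.4, i_d = 0), base)),
         do.call(ssm_params, c(list("SNFI", i_v = 0.4), base))),
    list(do.call(ssm_params, c(list("SCA", i_v = 0, i_d = 0.02), base)),
         do.call(ssm_params, c(list("CA", i_d = 0.02), base))),
    list(do.call(ssm_params, c(list("SSCA", i_v = 0.4, i_d = 0.02, a = 1),
                               base)),
         do.call(ssm_params, c(list("SCA", i_v = 0.4, i_d = 0.02), base))),
    list(ssm_params("DCA", b = 0.3, g = 2, sigma = 2.5, s = 2, i_d = 0),
         ssm_params("DNFI", b = 0.3, g = 2, sigma = 2.5, s = 2)))
  for (pr in pairs) {
    a <- simulate_dataset(pr[[1]], design, seed = 42)
    b <- simulate_dataset(pr[[2]], design, seed = 42)
    expect_identical_datasets(a, b)
  }
})

test_that("choice probabilities respect stochastic dominance", {
  p <- reference_params("RACE")
  n <- 6000
  probs <- vapply(2:4, function(v) {
    d <- simulate_dataset(
      p, tibble::tibble(v_left = rep(v, n), v_right = rep(1, n)),
      seed = 100 + v)
    mean(d$choice == "L", na.rm = TRUE)
  }, numeric(1))
  # non-decreasing in the left value, with a 3-SE allowance
  expect_true(all(diff(probs) > -3 * sqrt(0.25 / n)))
})

test_that("published parameter sets rarely fail to cross by the horizon", {
  for (m in ssm_models()) {
    d <- simulate_dataset(reference_params(m), design_grid(1:4, 500),
                          seed = 9)
    expect_lt(mean(!d$crossed), 0.01, label = m)
  }
})

test_that("datasets round-trip through delimited text with provenance", {
  p <- reference_params("NDD")
  d <- simulate_dataset(p, design_grid(1:4, 5), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_behavior(d, path)
  r <- read_behavior(path)
  expect_identical_datasets(d, r)
  prov <- attr(r, "provenance")
  expect_equal(prov$model, "NDD")
  expect_equal(as.integer(prov$seed), 4L)
})
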