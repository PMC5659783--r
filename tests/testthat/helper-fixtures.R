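# Shared fixtures, computed lazily and cached for the session so that
# expensive simulations (the full model-row battery) run at most once per
# model across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Full-scale model-row reproduction (20,000 trials per input vector).
model_rows_for <- function(model, seed = 1) {
  cached(paste0("rows_", model, "_", seed),
         reproduce_model_rows(model, seed = seed))
}

# A small toy dataset with hand-countable cells: two value pairs, choice
# counts multiples of 10, distinct RTs.
toy_dataset <- function() {
  tibble::tibble(
    subject = 1L,
    trial = 1:40,
    v_left = rep(c(3L, 2L), each = 20),
    v_right = rep(c(1L, 2L), each = 20),
    # pair (3,1): 12 hi choices (L), 8 lo choices (R); pair (2,2): 20 trials
    choice = c(rep("L", 12), rep("R", 8), rep("L", 20)),
    rt_ms = c(seq(400, 1500, by = 100), seq(450, 1150, by = 100),
              seq(500, 2400, by = 100)),
    crossed = TRUE
  )
}

# Like toy_dataset() but with every per-choice count a multiple of 10 and
# distinct RTs, so empirical bin masses coincide exactly with the
# interpolated-quantile masses.
round_dataset <- function() {
  tibble::tibble(
    subject = 1L,
    trial = 1:40,
    v_left = rep(c(3L, 2L), each = 20),
    v_right = rep(c(1L, 2L), each = 20),
    choice = c(rep("L", 10), rep("R", 10), rep("L", 20)),
    rt_ms = c(seq(400, 1300, by = 100), seq(450, 1350, by = 100),
              seq(500, 2400, by = 100)),
    crossed = TRUE
  )
}

expect_identical_datasets <- function(a, b) {
  expect_equal(tibble::as_tibble(a)[names(b)], tibble::as_tibble(b)[names(b)],
               ignore_attr = TRUE)
}
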