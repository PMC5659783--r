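# valuessm

Sequential-sampling accumulator models for value-based binary choice.

## The problem

When people choose between two options on the basis of subjective value
(which snack would you rather eat?), both the choice and its reaction
time carry information about the underlying decision computation. This
package implements, simulates, fits, and compares a family of eight
nested connectionist accumulator models of that computation, for
researchers modeling two-alternative forced-choice data with trial-level
option values, choices, and RTs.

Every model shares the discrete-time rectified recurrence

    d_x(t + dt) = max{ 0, d_x(t) + f_x(t) + eps_x(t) },   eps ~ N(0, sigma^2)

for the decision signal of option `x`, updated in 10-ms steps from
stimulus onset until the first signal reaches the fixed threshold
`D = 100` (the crossing time is the RT). The value signal is a step
function rising from 0 to the latent value `V_x` after a 150-ms
predecision period; baseline input `b` and noise act from `t = 0`, so
starting-point variability is emergent. The models differ only in the
drift `f_x`:

| model | drift `f_x` | distinguishing mechanism |
|-------|-------------|--------------------------|
| RACE | `b + g v_x` | independent accumulators |
| NDD  | `b + g (v_x − v_other)` | perfect input competition (neural drift-diffusion) |
| SNFI | `b + g (v_x − i_v v_other)` | subtractive input competition |
| DNFI | `g (b + v_x)/(s + Σv)` | divisive input competition |
| CA   | `b + g v_x − i_d d_other` | lateral inhibition between accumulators |
| SCA  | `b + g (v_x − i_v v_other) − i_d d_other` | both competition levels |
| DCA  | `g (b + v_x)/(s + Σv) − i_d d_other` | divisive + lateral |
| SSCA | SCA with `v_x = V_x^a`, `a ≥ 1` | + supralinear attentional power law |

The SSCA model's power law is a static stand-in for attention's
winner-take-all positive feedback; it is the one mechanism in the family
that produces the empirically observed *overweighting of the
greater-valued option* in choices (a positive effect of the value sum on
accuracy).

Fitting uses a Monte-Carlo chi-square quantile method: data are reduced
to per-input-vector choice frequencies and 10/30/50/70/90% RT quantiles
(six bins per choice, responses under 300 ms discarded), predictions are
simulated (2,000 trials per input vector), and a Pearson-type statistic
with equal weight per input vector is minimized by Nelder–Mead with
calibrated randomized seeding. Model comparison offers likelihood-ratio
tests for nested pairs, AICc/BIC, and saturated/null benchmark
predictors. A regression battery mirrors the standard analysis of such
experiments: complementary logistic models of accuracy
(greater + lesser vs |difference| + sum of normalized values) and linear
models of RT per trial category with constant-normalized coefficients.

## Worked example

Simulate a study from the published SSCA parameter set, run the
analysis battery, and look for the model's signatures:

```r
library(valuessm)

params <- reference_params("SSCA")
study  <- simulate_dataset(params,
                           design_grid(values = 1:4, trials_per_vector = 2000),
                           seed = 1)
trials <- normalize_values(classify_trials(study), levels = 1:4)
dplyr::count(trials, category)
#>   category        n
#> 1 correct      9637
#> 2 incorrect    2357
#> 3 indifferent  7991

fit_accuracy(trials)
#>   outcome  parameterization term      estimate     se statistic   p_value
#> 1 accuracy greater+lesser   constant    -0.291 0.0763     -3.82 1.36e-  4
#> 2 accuracy greater+lesser   greater      3.16  0.130      24.4  2.76e-131
#> 3 accuracy greater+lesser   lesser      -2.71  0.131     -20.7  2.79e- 95
#> 4 accuracy difference+sum   constant    -0.291 0.0763     -3.82 1.36e-  4
#> 5 accuracy difference+sum   difference   2.94  0.121      24.3  6.88e-131
#> 6 accuracy difference+sum   sum          0.224 0.0493      4.54 5.55e-  6
```

Accuracy rises steeply with the greater value (log-odds 3.16 per
normalized value unit) and falls less steeply with the lesser value
(−2.71): the greater option is overweighted, so the value *sum* helps
accuracy (+0.224, p < 1e-5) — the attentional signature only SSCA
produces.

```r
fit_rt(trials, "correct")[, c("parameterization", "term", "estimate",
                              "normalized", "se_normalized")]
#>   parameterization term       estimate normalized se_normalized
#> 1 greater+lesser   constant     1.08       1.08         0.0108
#> 2 greater+lesser   greater     -0.313     -0.290        0.0132
#> 3 greater+lesser   lesser       0.144      0.133        0.0130
#> 4 difference+sum   constant     1.08       1.08         0.0108
#> 5 difference+sum   difference  -0.228     -0.212        0.0112
#> 6 difference+sum   sum         -0.0848    -0.0786       0.00686

category_rt_test(trials, "incorrect", "correct")
#>   mean_diff_ms statistic    df  p_value
#> 1         146.      19.1 3383. 4.13e-77
```

Mean correct-choice RT is 1.08 s; a maximal greater value speeds
responses by 29%, a maximal lesser value slows them by 13%, and both a
larger value difference (easier trial) and a larger value sum (more
motivational salience) speed responding. Errors are ~150 ms slower than
correct choices.

To fit a model to a dataset and compare candidates:

```r
halves <- parity_split(study)
obs    <- quantile_table(halves$training)
fit    <- fit_model("SCA", obs, seed = 1)   # ~20 restarts; use fewer to explore
glance(fit)                                  # chi2, AICc, BIC
tidy(fit)                                    # fitted parameters
```

A command-line interface wrapping the same functions ships at
`inst/cli/valuessm` (`simulate | fit | compare | analyze | recover |
tables`); every run writes a `manifest.json` that `replay_manifest()`
reruns byte-identically.

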