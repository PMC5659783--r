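---
title: "Accumulator models of value-based binary choice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulator models of value-based binary choice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuessm)
```

## The model family

valuessm implements a family of eight nested connectionist
sequential-sampling models of two-alternative forced choice between
options with independent subjective values (e.g., snack foods rated on a
small discrete scale). Each option `x` is represented by a decision
signal `d_x(t)`, initialized at zero at stimulus onset and updated in
discrete 10-ms steps by the shared rectified recurrence

    d_x(t + dt) = max{ 0, d_x(t) + f_x(t) + eps_x(t) },

with i.i.d. Gaussian noise `eps ~ N(0, sigma^2)` drawn independently per
alternative per step. The first signal to reach the fixed threshold
`D = 100` (an arbitrary scaling constant) triggers the response; the
crossing time is the reaction time. The value signal driving `f_x` is a
step function: zero during the biologically constrained 150-ms
predecision period, the latent value `V_x` thereafter. Because the
baseline input `b` and the noise act from `t = 0`, starting-point
variability emerges from predecision noise accumulation rather than from
an extra free parameter. Integration is perfect (no leak): recurrent
self-excitation and leakage are assumed balanced.

The models differ only in the drift term `f_x` (see `drift_increment()`):

| model | drift `f_x` | free parameters |
|-------|-------------|-----------------|
| RACE  | `b + g v_x` | b, g, sigma |
| NDD   | `b + g (v_x − mean of other v)` | b, g, sigma |
| SNFI  | `b + g (v_x − i_v Σ other v)` | + i_v |
| DNFI  | `g (b + v_x) / (s + Σ all v)` | + s |
| CA    | `b + g v_x − i_d Σ other d` | + i_d |
| SCA   | SNFI drift − `i_d Σ other d` | + i_v, i_d |
| DCA   | DNFI drift − `i_d Σ other d` | + s, i_d |
| SSCA  | SCA drift with `v_x = V_x^a` | + i_v, i_d, a |

RACE assumes complete independence between the channels; NDD is a
neurally-rectified drift-diffusion variant sensitive only to value
differences (SNFI with `i_v = 1`); SNFI/DNFI implement imperfect
subtractive or divisive input-dependent competition; CA implements
state-dependent competition (lateral inhibition between accumulators);
SCA/DCA combine both levels of competition; and SSCA adds a static
supralinear power law `v = V^a` (`a >= 1`) approximating attention's
winner-take-all positive feedback, which selectively amplifies
higher-valued options. Constraints: `b >= 0`, `g > 0`, `sigma >= 0`,
`0 <= i_v <= 1`, `s > 0`, `0 <= i_d <= 1`, `a >= 1`.

Timing conventions (all choices fixed, not fitted): threshold 100, step
10 ms, value-signal onset 150 ms, horizon 3000 ms (the emulated task's
response window). An update from `t` to `t + dt` uses the value signal
at `t`, so with a noiseless unit-gain race and `V = (100, 50)` the first
alternative crosses at exactly 160 ms. `sigma` is the standard deviation
of the increment per 10-ms step; simulating at another `dt` without
rescaling `sigma` by `sqrt(dt / 10 ms)` is off-label. Ties (both signals
crossing on one step) are broken uniformly at random; there is no
post-crossing motor constant. Trials that have not crossed by the
horizon are flagged and excluded downstream (at the published parameter
sets fewer than 1% of trials time out; the emulated task forced a
computer-random choice on such trials, which is not modeled).

The latent values entering the model are the raw rating ranks (1–4 for
the 4-level design); the gain `g` absorbs the scale. The regression
analyses, by contrast, use values normalized to [0, 1] so coefficients
are comparable across rating scales.

## Simulation engine

`simulate_dataset()` runs a compiled (Rcpp) trial loop; `simulate_trial()`
is a pure-R reference path built from the exported per-step operations.
Both consume R's RNG in the same order — Gaussian deviates are produced
by Box–Muller pairs on the uniform stream, one pair per two alternatives
— so the two routes are bit-identical under a shared seed, and one seed
integer fully determines any simulated dataset. This dual-route design
lets the test suite validate the fast path against the transparent one
exactly, not just statistically.

## Chi-square quantile fitting

Fitting compares data and model at the level of per-input-vector
summaries (`quantile_table()`): for each of the 10 unordered value pairs,
the frequency of choosing the higher-valued option and the 10/30/50/70/90%
quantiles of each choice's RT distribution (six bins per choice).
Responses faster than 300 ms are treated as contaminants and dropped
everywhere — in empirical and simulated data alike, so model rows and
data rows are computed identically. Quantiles interpolate linearly
between order statistics (R type 7), making summaries bit-reproducible.
Equal-value pairs carry no choice information and form a single
category; choices with fewer than 5 trials in a cell contribute their
frequency only, since quantiles of tiny samples are unstable.

The objective (`chi2_statistic()`) is a Pearson-type statistic on those
bins: observed masses are `(0.1, 0.2, 0.2, 0.2, 0.2, 0.1)` times the
choice frequency; predicted masses are the fraction of simulated trials
(2,000 per input vector by default) falling into each bin; each input
vector receives equal weight through a common effective count
`n_eff = total responded trials / number of vectors`; and predicted
proportions are floored at `1e-4` so empty predicted bins stay finite.

`fit_model()` minimizes this objective with Nelder–Mead under bound-
enforcing reparameterizations (log for positive parameters, logit for
the inhibition weights, shifted log for `a - 1`), with common random
numbers within each simplex round so the surface the simplex sees is
deterministic. Three design elements matter on this noisy, rough
surface, and each is there because its absence demonstrably breaks the
search:

* *Calibrated randomized seeding.* Each restart screens a pool of random
  candidate starts whose gain is moment-matched so the noiseless first
  passage of the mean input lands near the observed median RT; the
  simplex starts from the best candidate. Unscaled random starts spend
  the entire iteration budget at absurd time scales.
* *Profile stage.* For every model beyond the race and drift-diffusion
  variants, a coarse grid over the structural parameters is laid down
  first — competition weights and attentional exponent, plus the
  baseline for the divisive models, whose normalized baseline spans
  orders of magnitude — with the remaining well-conditioned parameters
  profiled out by a short low-fidelity simplex at each grid point; the
  best grid points join every restart's screening pool. This is the
  standard profile-the-nuisance strategy for multimodal surfaces:
  started blind, the simplex reliably lands in mimicry valleys (e.g.
  small `a` with inflated gain) whose objective is three times the true
  minimum.
* *Rotating noise streams and out-of-sample restart selection.* Each
  restart runs several simplex rounds from the running incumbent, each
  round under a fresh common-random-number stream, and every round
  re-inflates the simplex with uniform steps on the transformed scale
  (sizing steps by coordinate magnitude would collapse them near zero).
  A simplex left on one stream learns to exploit that particular noise
  realization — its apparent chi-square can sit far below the expected
  value — and such spurious minima do not survive a stream change.
  For the same reason restarts are compared, and the final chi-square
  reported, on validation streams independent of every restart's search
  stream.

The default budget (20 restarts, 400 iterations each) is a deliberate
config knob; the tests use leaner, documented budgets.

Benchmarks: the saturated predictor reuses the training summary directly
(piecewise-linear RT distribution through the five quantiles), so its
in-sample chi-square is exactly zero by construction; the null predictor
uses one mean choice frequency and one uniform RT distribution over the
averaged per-cell range. `information_criteria()` treats the chi-square
as a deviance proxy (`AICc = chi2 + 2k + 2k(k+1)/(n−k−1)`,
`BIC = chi2 + k ln n` with `n` the number of bin cells actually entering
the objective — a choice that shifts all models' criteria jointly and
cannot reorder equal-`n` comparisons). `lr_test()` refers chi-square
differences of nested fits to a chi-square law, clamping rare negative
differences (Monte-Carlo noise) to zero with a warning. Whether the
original analyses used the chi-square difference or a true likelihood
ratio is not documented; the package adopts the former and says so here
rather than claiming equivalence. `parity_split()` reproduces the
train/test partition rule: odd trials of odd subjects plus even trials
of even subjects form the training half.

## The regression battery

`classify_trials()` labels trials correct (greater value chosen),
incorrect, or indifferent (equal values; accuracy undefined, so these
enter only the sum-only RT model). `fit_accuracy()` fits two
complementary logistic models on normalized values — greater + lesser,
and |difference| + sum, orthogonal linear recombinations of the same
inputs. `fit_rt()` fits the analogous linear models of RT in seconds per
category, and reports each non-constant coefficient divided by the
constant term (a normalized coefficient of −0.1 means a 10% speed-up at
that regressor's maximum); the constant itself is reported raw in
seconds. The normalized coefficient's standard error is the raw SE
divided by the constant estimate, ignoring the intercept's own
uncertainty — the delta-method cross-term is negligible at these sample
sizes and the original reports give no more detail. Two-tailed tests are
used throughout. `abs_contrast()` compares coefficient magnitudes
(`M = |b1| − |b2|`) with combined standard errors, and
`meta_aggregate()` pools regression tables across datasets with weights
proportional to trial counts, deriving the aggregate SE from the
weighted between-dataset variance of the estimates (how the original
aggregate SEs were computed is not documented; this choice is ours).

The complementary parameterizations guard against mimicry: a pure
greater-value effect of size `c` masquerades as difference and sum
effects of `c/2` each. The signature patterns the battery exposes: only
the supralinear attentional model (SSCA) produces the empirically
observed *positive* accuracy–sum effect (overweighting of the greater
value); perfect input competition (NDD) is structurally blind to the
value sum in RT; and the independent race exhibits statistical
facilitation — both values speed RT, so the sum effect dominates the
difference effect.

## Synthetic designs and validation experiments

`make_design()` emulates the modeled task's balanced design: 720 trials
per subject spread equally over the 10 unordered pairs of a 4-level
scale (which balances value differences 0–3 in the ratio 4:3:2:1), the
side of the greater value counterbalanced within each pair, randomized
order with no identical pair on consecutive trials. `generate_study()`
composes designs and simulation into multi-subject datasets suitable for
the parity split, fitting, and the battery. No subject heterogeneity is
generated: the original analyses concatenate trials across subjects, so
the generator's single parameter set per study matches what the fitting
assumes. Features of real data the generator deliberately omits —
rating noise, fatigue and sequential effects, condition differences,
trial-to-trial parameter variability — mean that passing tests validate
the computational pipeline, not the biology.

`reproduce_model_rows()` is the canonical regression test: it simulates
20,000 trials per input vector at the published fitted parameters
(`reference_fits()`), runs the exact battery, and compares against the
stored published coefficients (`reference_model_rows()`) in units of the
published standard errors. With 200,000 fresh trials per model our
Monte-Carlo error matches the published rows' own, so agreement within
about 3 published SEs is the expected resolution.
`recovery_experiment()` simulates data at known parameters at the study
scale (2,000 trials per vector), refits, and reports per-parameter
relative errors; the competition weights of the hybrid models trade off
against gain and exponent (documented in the restart logs), so recovery
is judged on the median across parameters.

## Numerical choices and problem sizes

Degenerate inputs: zero-noise parameter sets are rejected as unfittable
(sigma sits on a boundary and RT distributions collapse); empty cells
after the 300-ms filter are excluded from the objective; perfect
separation in the logistic fits and categories with fewer than 10 trials
in the RT fits yield flagged, coefficient-free tables rather than
numbers. The test suite sizes its simulations to what the checks need
statistically — tens of trials for exact identities, a few thousand for
distributional properties, the full 20,000 per vector only for the
published-row comparisons — and the fitting tests use the documented
lean optimizer budgets (1–2 restarts) rather than the 20-restart default
appropriate to a real analysis.

## Known limitations

Only the two-alternative case is validated, although the general-`n`
equations are implemented (the NDD "max-minus-average" generalization is
exposed but untested beyond `n = 2`). The execution stage is reduced to
the threshold-crossing event. There are no leak/self-excitation
imbalance, urgency gating, collapsing bounds, or trial-level parameter
variability. The empirical datasets behind the published tables are not
redistributed here; the package regenerates the model-predicted rows
and validates everything else by construction on synthetic data.
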