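---
title: "Attention-LSTM incidence forecasting with swarm-tuned hyperparameters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-LSTM incidence forecasting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asircast)
```

## The problem

Cancer registries and burden-of-disease consortia publish annual
age-standardized incidence rates (ASIR, new cases per 100,000 person-years)
stratified by sex and 5-year age band. Public-health planning wants multi-year
forecasts of every stratum at once: the 24 series (2 sexes x 12 bands from
40--44 to the open-ended 95+) move together — shared screening policy, shared
risk-factor history — so forecasting them jointly is both statistically
efficient and operationally what a planner needs.

`asircast` implements one concrete architecture for this task: a single-layer
LSTM encoder reads a sliding window of `w` consecutive years of all `S`
strata, an additive-attention layer pools the per-year hidden states into a
context vector, and a single affine head emits all `h x S` future values in
one shot. The four training hyperparameters are selected by particle swarm
optimization (PSO) against expanding-window time-series cross-validation.

## Model

With `x_t` the length-`S` vector of z-scored rates in year `t`, the encoder
iterates the standard gate equations on the concatenation `[h_{t-1}, x_t]`:

$$
\begin{aligned}
f_t &= \sigma(W_f [h_{t-1}, x_t] + b_f), \quad
i_t = \sigma(W_i [h_{t-1}, x_t] + b_i), \quad
o_t = \sigma(W_o [h_{t-1}, x_t] + b_o),\\
C_t &= f_t \odot C_{t-1} + i_t \odot \tanh(W_C [h_{t-1}, x_t] + b_C), \qquad
h_t = o_t \odot \tanh(C_t),
\end{aligned}
$$

from zero initial state. Attention scores each hidden state with
$e_t = v^\top \tanh(W_a h_t + b_a)$, normalizes
$\alpha_t = \mathrm{softmax}(e)_t$, and pools $a = \sum_t \alpha_t h_t$. The
head is one affine map $\hat{y} = W_y a + b_y$ reshaped to `h x S` — no
recursive feeding of predictions, so errors do not accumulate across the
horizon and cross-stratum co-movement is learned directly in `W_y`.

Training minimizes mean squared error over all `h x S` outputs (z-units) plus
an L2 penalty on the weight matrices, with Adam, seeded mini-batch shuffling,
and early stopping on validation MSE (patience 5, best-epoch weights
restored, cap 100 epochs). All of this — forward pass, backpropagation
through time, Adam — is implemented in plain R matrix code; there is no deep
learning backend underneath, which keeps the package dependency-free and the
gradients testable against finite differences.

## Parameters that matter

| knob | range / default | meaning |
|---|---|---|
| `w` | 10 years | history window the encoder reads |
| `h` | 5 years | forecast horizon, emitted in one shot |
| `hidden_units` | 16--64 (tuned) | LSTM state dimension |
| `dropout_rate` | 0--0.4 (tuned) | inverted dropout on pooled hidden states, training only |
| `learning_rate` | 1e-4--1e-2, log scale (tuned) | Adam step size |
| `batch_size` | 16--64 (tuned) | mini-batch size |
| `l2` | 1e-4 | L2 coefficient (never stated by the method's source; exposed in config) |
| swarm | 10 particles, 50 generations, c1 = c2 = 2, inertia 0.9 -> 0.5 | PSO budget |
| `inner_epochs` | 30 | epoch cap inside the CV fitness (see below) |

Normalization is per stratum — `(x - mu_s) / sigma_s` with population-SD
`sigma_s` — because the 24 series span two orders of magnitude and a global
scale would crush the younger bands. Within cross-validation the statistics
are fitted on each fold's training years only; the final model fits them on
all years. The population-SD estimator is fixed (not sample SD) so tests are
exact.

## Cross-validation and the PSO fitness

Folds are calendar-anchored and strictly chronological. For a panel covering
1990--2021 they are 1990--2005 -> 2006--2010, 1990--2010 -> 2011--2015,
1990--2015 -> 2016--2020; for other spans the same construction is applied
with 5-year validation blocks ending at the last year that completes a block
(a trailing partial year is unused). Validation windows draw their input
context from the tail of the training years; every target year lies inside
the validation block, and the package tests assert that perturbing any year
after a fold's validation range changes neither the normalization parameters
nor the fitness.

The PSO fitness of a candidate hyperparameter vector is the mean z-unit
validation MSE over the three folds, each fold trained with an inner epoch
cap of 30 (default). The cap is a deliberate config knob: the method's source
reports a total tuning cost consistent with truncated inner training but
never states the budget, so it is exposed rather than guessed at 100.

## The swarm

Velocities and positions follow the canonical update
`v <- omega v + c1 r1 (p - x) + c2 r2 (g - x)`, `x <- x + v`, with inertia
annealed linearly 0.9 -> 0.5, `c1 = c2 = 2`, 10 particles, at most 50
generations, and a stall rule (no global-best improvement > 1e-9 for 5
generations). Design choices where conventions genuinely differ:

* `r1`, `r2` are **scalar** uniforms per particle per term — the literal
  reading of `rand()` in the source's pseudocode. The per-dimension variant
  was implemented first and measurably slowed convergence (sphere benchmark
  median ~2e-3 rather than ~2e-4 at the production budget); the scalar
  reading is both more faithful and better behaved.
* Velocities are clamped to half the per-dimension range (the classical
  `Vmax = Xmax` rule) and positions clipped to bounds.
* Integer dimensions (hidden units, batch size) are searched continuously and
  rounded at decode time; a fitness cache keyed on the decoded configuration
  avoids retraining identical rounded candidates.
* The learning rate is searched in log10 space.
* Evaluation order matches the pseudocode: evaluate all particles, update
  bests, then move.

A failing fitness evaluation scores the particle `+Inf` and is logged instead
of aborting the search.

## Synthetic panels: what they emulate, what they do not

There is no bundled registry extract; the generator is first-class, tested
code that stands in for one. Its expectation surface is

$$
E[x_{t,(sex, a)}] = \text{base} \cdot e^{\text{slope} \cdot a} \cdot
\text{roll}(a) \cdot \text{ratio}(sex) \cdot \text{trend}_a(t),
$$

with defaults chosen once to mimic the published shape of lung-cancer ASIR
panels: female 40--44 base rate 6 per 100,000; log-age slope 0.42 per 5-year
band (about x1.5 per band, spanning 6 to ~900 across the 12 bands); a 0.45
rolloff multiplier on the open-ended 95+ band (the drop visible in published
tables); male/female ratio 2.2; and a per-stratum logistic rise-and-plateau
trend (multiplier 0.7 -> 1.3, time scale 4 years) whose midpoint shifts one
year per age band so different strata have genuinely different informative
periods — which is what gives attention something to attend to. Noise is
multiplicative mean-one lognormal (rates are positive and dispersion grows
with level), default CV 5%.

What the generator does **not** emulate: cohort effects, period shocks
(screening roll-outs, classification changes), autocorrelated measurement
error, and the GBD's model-based smoothing. A green end-to-end test therefore
establishes that the pipeline recovers a smooth, monotone-in-age,
plateauing world it has never seen labels for — not that it forecasts real
registry data at any particular accuracy.

## Numerical choices

* Weight initialization: scaled uniform (`1/sqrt(fan-in)`), forget-gate bias
  1 (so early training does not erase the cell state), everything else 0;
  all seeded.
* Softmax scores are max-shifted before exponentiation.
* Dropout is inverted (scaled at train time) and applied to the pooled hidden
  states only; inference is a pure deterministic function of window and
  parameters.
* The attention score dimension equals `hidden_units` — the smallest choice
  that adds no new search dimension; the head consumes the context vector
  alone, following the source's equation over its looser prose.
* Early stopping treats "no improvement" as `< 1e-12` absolute; PSO stalls at
  `< 1e-9`; both exposed.
* `mape` refuses zero actuals and `nrmse`/`r2` refuse constant actuals — no
  silent epsilons.
* ARIMA(0,2,0) has no parameters; when `stats::arima` fails the identical
  closed form (extend the last linear trend) is used and logged.
* Comparison metrics for report tables are computed in original rate units
  (a MAPE on rates is interpretable; one on z-scores is not), while the PSO
  fitness uses z-unit MSE as the pseudocode states. Both modes exist and
  neither is claimed to reproduce any published table's absolute values.

## Counting convention

A 32-year, 24-stratum panel windowed at `w = 10`, `h = 5` yields
`32 - 10 - 5 + 1 = 18` multivariate windows; multiplying by the 24
subsequences gives the per-subsequence count of 432 that the method's source
reports alongside a declared `(10, 24)` input shape. The package trains on
the 18 multivariate windows (matching the declared shape) and exposes both
numbers through `count_samples()` so the discrepancy is surfaced, not hidden.

## Ablation and baselines

`run_ablation()` evaluates four variants — plain LSTM, LSTM + attention,
LSTM + PSO (attention off), and the full model — on bit-identical folds,
normalization and seeds; non-tuned variants use the midpoint hyperparameters
(hidden 40, dropout 0.2, lr 1e-3, batch 32). `fit_predict_baseline()` adds
per-stratum ARIMA(0,2,0), RBF-kernel epsilon-SVR (gamma 0.1, C 10) and a
bagged regression forest (100 trees, depth 10), all scored on the same
validation cells. SVR and the forest consume flattened lag-`w` windows per
stratum (one regressor per horizon step) so that the comparison isolates the
model class; because no SVR or random-forest package ships with the target
environment, both are minimal from-scratch implementations (exact
coordinate-descent dual solver; variance-reduction CART with bootstrap and
`mtry = floor(p/3)`).

## Known limitations

* Pure-R training is fast at this problem size (a full training run is
  ~1--3 s) but would not scale to long sequences or wide panels.
* Exact reproducibility is promised for a fixed seed on a fixed BLAS; across
  BLAS builds agreement is statistical, not bitwise.
* No uncertainty intervals; point forecasts only.
* The CV design fixes 5-year validation blocks; other horizons require
  `val_len` adjustments and are only lightly tested.
* The end-to-end acceptance test runs the genuine pipeline at a reduced
  search budget (6 particles x 4 generations, inner cap 20) so the suite
  fits a single-CPU CI budget; the production defaults (10 x 50, inner 30)
  exercise the identical code path.
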