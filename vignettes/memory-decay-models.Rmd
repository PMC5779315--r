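---
title: "Direct versus coded storage: models of short-term memory decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct versus coded storage: models of short-term memory decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmbound)
library(dplyr)
```

## The scientific question

In delayed-estimation psychophysics a subject briefly views K oriented
bars, waits T seconds, and reproduces the orientation of one probed item
on a continuous dial. Recall error grows with both the delay and the
number of items. If short-term memories are held as graded persistent
activity on continuous attractor networks, neural noise makes the stored
value drift diffusively: its squared error grows linearly in time at rate
2D, where D is the network diffusivity. `stmbound` implements and
compares two accounts of how that microscopic drift maps onto behavior.

**Direct storage.** Each of the K orientations is parked, untransformed,
in its own attractor network. Splitting N units of neural resource across
K networks leaves each with N/K, and diffusivity scales inversely with
resource, so the pooled diffusivity is D·K/N and

$$\mathrm{MSE}(K, T) = \Phi^2 \, 2D \frac{K}{N} T ,$$

linear in delay and set size, with the single free parameter
ρ = N/2D (seconds). All quantities are normalized: the orientation range
Φ = 1 corresponds to 180°, so squared errors are dimensionless and capped
at 1/4 (`norm2_to_deg2()` converts back).

**Coded storage.** Storage in noisy networks is a noisy channel; an
encoder may add redundancy before storage and a decoder may error-correct
afterwards. Treating each of N networks as an additive Gaussian channel
of noise variance 2DT, the per-item information rate under equal
allocation is bounded by (N/2K)·log(1 + 1/(2DT)) nats, and
rate–distortion theory for a uniform source turns that rate into a floor
on achievable error:

$$\mathrm{MSE}(K, T) \ge \frac{\Phi^2}{2\pi e}
  \left(1 + \frac{1}{2DT}\right)^{-N/K} .$$

Set size sits in the exponent, so performance degrades much faster with
items than with delay — the qualitative signature that separates the two
models in data. The two free parameters are N and 1/2D (seconds); their
product N/2D is the same combined neural-resource measure as in the
direct model. Natural logarithms are used throughout (bits differ by
log 2). The bound is evaluated in the log domain, so large N/K cannot
underflow; the T = 0 limit is 0 by continuity of the infinite-SNR limit.

```{r theory}
spec <- channel_spec(n_items = 6, n_channels = 10,
                     diffusivity = 1 / (2 * 2.28), duration = 3)
direct_storage_mse(spec)
coded_storage_mse_bound(spec)
```

The package checks, as a standing invariant, that the closed-form bound
equals the composition of `per_item_rate()` and
`rate_distortion_interval()` to 1e-12 relative error across the parameter
space, and that the heuristic capacity/e^(-2I) identity holds.

## The diffusion channel

`simulate_diffusion()` realizes the storage noise as Brownian motion on a
circle — no restoring force, because drift runs along the flat manifold
of attractor states. Increments are exact Gaussians of variance 2D·dt, so
the default stepping (dt = T/1000) only sets time resolution; an exact
single-step sampler serves large ensembles. Displacements are wrapped to
(−C/2, C/2], matching the signed-error convention of the empirical
module. The simulator grounds two assumptions the closed forms rely on:
squared displacement grows as 2DT while 2DT ≪ C², and saturates at the
wrapped-uniform second moment C²/12 beyond; and
`simulate_direct_storage()` confirms the D·K/N pooling rule by Monte
Carlo. `estimate_diffusivity()` inverts the process by a through-origin
regression of mean squared displacement on time — valid only in the
unsaturated regime, which is where all fits live.

The coding argument treats the channel noise as linear additive Gaussian
while responses live on a circle; the two coincide in the unsaturated
regime, and all quantitative comparisons are made there.

## The synthetic experiment

`generate_dataset()` emulates the design the models are meant for: 10
subjects, set sizes {1, 2, 4, 6}, delays {0.1, 1, 2, 3} s, 11–15 blocks
of 80 trials per subject (drawn uniformly per subject), each block
holding exactly 5 trials per (K, T) cell; targets uniform on [0, 180)°;
item colors drawn from 8 distinguishable colors as bookkeeping
(misbinding is not simulated). With block counts free in 11–15, per-cell
totals vary around ~650 trials per (K, T) pair across 10 subjects;
configure `blocks_range` if an exact total is needed.

Responses are the target plus wrapped-normal noise. The target second
moment of a cell is `baseline(K) + D(K, T) − D(K, T0)` with T0 = 0.1 s:
baseline errors at the shortest delay (perception, encoding limits) are
treated as an independent additive variance, exactly the anchoring
convention the fitting stage uses, so generated data satisfy it by
construction. Because a wrapped normal's circular second moment falls
slightly below its underlying σ², the generator solves for σ by moment
matching (`E[wrap(ε)²]` equals the target), keeping per-cell MSE
estimates unbiased for the model curve at any noise level; targets at or
above the circular ceiling C²/12 trigger a saturation warning and fall
back to the wrapped-uniform limit. Default baselines rise from 0.0015 to
0.012 normalized units² (about 7–20° RMS) from 1 to 6 items — typical
short-delay precision in this paradigm; they are a fixed choice, not a
fitted quantity.

What the generator does *not* emulate: misbinding/swap responses,
guessing pedestals, attention lapses, and any departure of real response
distributions from wrapped normality. Passing tests therefore validate
the pipeline's statistical machinery, not the behavioral adequacy of
either model on human data.

## Summaries and anchored fitting

`performance_table()` computes per-cell normalized MSE as the unweighted
mean of per-subject means, with the SEM taken across participants — the
mean lives on the same structure as its error bar. The trial-pooled mean
is available behind `pooled = TRUE`; the two coincide on balanced
designs. The pooled per-trial variance of squared errors (`var_norm`) is
carried separately for the comparison likelihood. The boundary tie at a
90° error maps to +90° for determinism.

Fits anchor every curve to the empirical baseline:
`pred(K, T) = mse(K, T0) + D(K, T) − D(K, T0)`. Baseline cells
contribute zero residual by construction and are excluded from the loss.
Anchoring uses the difference of the curve at T and T0 rather than the
curve at T − T0; for the direct (linear) model the two coincide, for the
coded bound they differ slightly and the difference form keeps the
generator and fitter exactly consistent.

Weights multiply squared residuals and default to 1/SEM, as stated;
`weight = "inv_var"` gives the conventional 1/SEM² and `"ols"` unit
weights. A global SEM rescale leaves every argmin unchanged. Cells with
zero SEM abort with a pointer to `sem_floor`.

The direct model's loss is exactly quadratic in θ = 1/ρ, so
`fit_direct()` solves it in closed form (tests cross-check against a
bounded scalar optimizer). `fit_coded()` evaluates the weighted SSE on a
log-spaced grid — defaults N ∈ [1, 10³], 1/2D ∈ [10⁻², 10³] s, 200
points each — and refines the grid argmin by Nelder–Mead in
log-parameter space; ties break to the smallest N, then smallest 1/2D.
The landscape has a long, nearly flat valley: many (N, 1/2D) pairs fit
almost equally well, and what the data pin down tightly is the resource
product N/2D along it. `fit_coded()` therefore also returns the per-N
valley and the resource along it; `autoplot()` on the surface and
`plot_valley()` display them. `fit_direct_6item_ols()` reproduces the
single-curve variant (unit weights, largest set size only), which
over-predicts low-K errors whenever the large-K curve is steeper than
the shared-resource law allows. `jackknife_fits()` refits after leaving
out each subject and reports the jackknife SE.

```{r fits}
trials <- generate_dataset(
  experiment_design(),
  generative_model("coded", n_channels = 10, inv2d = 2.28),
  seed = 42
)
tab <- performance_table(trials)
fit_coded(tab, n_grid = logspace(1, 1e3, 100),
          inv2d_grid = logspace(1e-2, 1e3, 100))
```

## Model comparison

The comparison likelihood takes each trial's normalized squared error as
the observation; within a cell it is modeled as Gaussian with mean given
by the model's anchored prediction and variance given by the empirical
pooled variance of squared errors — shared by both models, so only the
means differ. The observable is a per-trial quantity whose cell mean is
exactly what the theories predict; treating its distribution as Gaussian
is an approximation (a squared error is skewed), adequate here because
both models face the same likelihood family. BIC uses the penalty
k·log(2πn) (the `"standard"` k·log(n) is a flag away); k = 1 for direct,
2 for coded, and counting the four anchored baselines in both models
shifts both penalties equally, leaving ΔBIC unchanged — an exact
invariance the tests assert. By default n is the number of observations
entering the likelihood; `n_obs` overrides it (e.g. a fixed per-cell
count). Positive ΔBIC = BIC(direct) − BIC(coded) favors coded storage,
with 10 the customary "very strong" cutoff. `point_pvalues()` gives the
per-cell two-sided Gaussian p-values of the data means around each
model's predictions.

## Numerical choices and problem sizes

* All stochastic checks fix seeds; identical configuration and seed
  reproduce datasets and ensembles bit-for-bit.
* Monte-Carlo assertions use 4 standard errors; parameter-recovery
  checks run 20 independent datasets at the full design size
  (~10,400 trials each) and test the median, which the suite completes
  in well under a minute; generator-fidelity checks use 10⁵ trials per
  cell.
* The coded-fit grid search is exact on its grid; refinement tolerance
  is `reltol = 1e-12`. Degenerate inputs (zero diffusivity, zero-noise
  generators, empty subsets, header-only CSV files) are defined and
  tested rather than rejected.
* A direct-model resource of ρ = 1215 s and coded parameters N = 10,
  1/2D = 2.28 s (resource 22.8 s) are used as the default study
  conditions for synthetic data; published analyses in this paradigm
  report the direct model needing roughly 40-fold more resource than the
  coded bound, and the defaults reproduce that contrast. We note the
  literature also quotes a direct-model slope parameter (2D/N ≈ 3.2×10⁻⁷)
  whose units are not reconcilable with the resource value above under a
  single seconds/normalized convention; this package works in normalized
  units and seconds throughout and treats the resource form as canonical.

## Limitations

The package adjudicates between two specific theories under a Gaussian
likelihood on squared errors; it does not fit trial-level mixture models
(swap/guess components), does not construct encoders achieving the
bound, and its bound is asymptotic in N — for small N it is a strict
floor, so a real memory system may sit above it even with optimal
coding. Conclusions drawn from synthetic data inherit the generator's
idealizations listed above.
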