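# stmbound

Short-term memory for analog variables decays with storage time and with
the number of items held. If memories live as graded persistent activity
on continuous attractor networks, neural noise makes each stored value
drift diffusively — squared error growing as 2𝒟T. `stmbound` implements
and adjudicates between two theories of how that drift maps onto human
delayed-estimation performance:

* **Direct storage** — each of K items occupies its own attractor
  network; splitting N resource units across K networks pools the
  diffusivity to 𝒟K/N, so

  MSE(K, T) = Φ² · 2𝒟 (K/N) T,

  linear in delay and set size, with a single free parameter
  ρ = N/2𝒟 (seconds).

* **Coded storage** — the K items are first encoded into an
  N-dimensional codeword; joint source–channel coding over the N
  Gaussian channels (noise variance 2𝒟T each) gives the lower bound

  MSE(K, T) ≥ Φ²/(2πe) · (1 + 1/(2𝒟T))^(−N/K),

  with set size in the exponent, and two free parameters N and
  1/2𝒟 (seconds) whose product N/2𝒟 is the same neural-resource measure
  as in the direct model.

The package is a tidyverse-style pipeline for the whole analysis:
closed-form theory (`direct_storage_mse()`, `coded_storage_mse_bound()`,
capacity and rate–distortion primitives), a wrapped-Brownian simulator
of the storage channel (`simulate_diffusion()`), a synthetic
delayed-estimation dataset generator emulating a 10-subject, 4-set-size,
4-delay design (`generate_dataset()`), per-(K, T) performance summaries
(`performance_table()`), anchored weighted-least-squares fitting with a
full (N, 1/2𝒟) error-surface and valley (`fit_direct()`, `fit_coded()`,
`jackknife_fits()`), and BIC model comparison (`compare_models()`).
Fitted objects support `tidy()`/`glance()` and `autoplot()`.

It is intended for computational and cognitive neuroscientists modelling
working-memory precision, and as a reusable reference implementation of
the information-theoretic bound.

## Worked example

Generate a synthetic experiment from the coded model (N = 10,
1/2𝒟 = 2.28 s), summarize it, fit both theories, and compare:

```r
library(stmbound)

trials <- generate_dataset(
  experiment_design(),                                  # 10 subjects, K ∈ {1,2,4,6}, T ∈ {0.1,1,2,3} s
  generative_model("coded", n_channels = 10, inv2d = 2.28),
  seed = 42
)
tab <- performance_table(trials)
tab
#> # performance_table: baseline delay 0.1 s
#> # A tibble: 16 × 7
#>   set_size delay_s mse_norm  sem_norm   var_norm n_trials n_subjects
#>      <int>   <dbl>    <dbl>     <dbl>      <dbl>    <int>      <int>
#> 1        1     0.1  0.00158 0.0000985 0.00000512      610         10
#> 2        1     1    0.00150 0.0000879 0.00000426      610         10
#> ...

fit_d <- fit_direct(tab)
fit_d
#> <direct storage fit>
#>   rho = N/2D = 1100 s
#>   weighted SSE = 0.287718 (inv_sem weights)

fit_c <- fit_coded(tab)
fit_c
#> <coded-storage bound fit>
#>   N = 6.943, 1/2D = 3.735 s, resource N/2D = 25.93 s
#>   weighted SSE = 0.0271738 (inv_sem weights)

compare_models(trials, fit_d, fit_c, table = tab)
#> <model comparison: direct vs coded storage>
#>   BIC direct = -44661.79 (k = 1)
#>   BIC coded  = -46074.47 (k = 2)
#>   delta BIC  = 1412.68 (positive favors coded storage)
```

Reading the output: `mse_norm` is squared recall error normalized by
(180°)², so 0.00158 at one item and 100 ms corresponds to about 7° RMS.
The coded fit's weighted SSE is an order of magnitude below the direct
fit's, and ΔBIC ≫ 10 decisively favors the coded model — as it should,
since the data were generated from it. The fitted (N, 1/2𝒟) sit on a
nearly flat valley; the well-identified quantity is the resource
N/2𝒟 ≈ 26 s against a generating value of 22.8 s
(`autoplot(fit_c$surface, fit_c$valley)` and `plot_valley(fit_c$valley)`
show the landscape).

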