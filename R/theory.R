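# Closed-form theory: the two competing models of delayed-estimation error.
#
# Direct storage: K circular variables are parked, one each, in K
# continuous-attractor networks sharing N units of neural resource.  Each
# network's state diffuses, so squared recall error grows linearly in time
# with pooled diffusivity D*K/N.
#
# Coded storage: the K variables are first encoded into an N-dimensional
# codeword and stored in N networks of diffusivity D each.  Joint
# source-channel coding over the resulting additive Gaussian channels gives
# a lower bound on achievable recall error that is exponential in N/K.

#' Parameter bundle for the memory-channel models
#'
#' Collects the quantities both theory curves are built from: the variable
#' range `phi` (normalized; 1 corresponds to the 180-degree orientation
#' range), the number of stored items `K`, the number of parallel memory
#' channels `N` (treated as a positive real; integer values are a
#' presentation convention), the per-channel diffusivity `D` in normalized
#' range squared per second, and the storage duration `T` in seconds.
#'
#' @param phi Variable range in normalized units (default 1).
#' @param n_items Set size `K`, at least 1.
#' @param n_channels Number of memory channels `N`, positive real.
#' @param diffusivity Diffusivity `D` (normalized units^2 / s), positive.
#' @param duration Storage duration `T` in seconds, nonnegative.
#' @return An object of class `channel_spec`: a named list of the five
#'   parameters plus the derived signal-to-noise ratio `snr = 1/(2*D*T)`
#'   (`Inf` at `T = 0`).
#' @export
#' @examples
#' channel_spec(n_items = 6, n_channels = 10, diffusivity = 1 / (2 * 2.28),
#'              duration = 3)
channel_spec <- function(phi = 1, n_items, n_channels, diffusivity, duration) {
  if (!is.numeric(phi) || phi <= 0) abort("`phi` must be positive.")
  if (!is.numeric(n_items) || any(n_items < 1)) {
    abort("`n_items` must be at least 1.")
  }
  if (!is.numeric(n_channels) || any(n_channels <= 0)) {
    abort("`n_channels` must be positive.")
  }
  if (!is.numeric(diffusivity) || any(diffusivity <= 0)) {
    abort("`diffusivity` must be positive.")
  }
  if (!is.numeric(duration) || any(duration < 0)) {
    abort("`duration` must be nonnegative.")
  }
  structure(
    list(
      phi = phi, n_items = n_items, n_channels = n_channels,
      diffusivity = diffusivity, duration = duration,
      snr = ifelse(duration > 0, 1 / (2 * diffusivity * duration), Inf)
    ),
    class = "channel_spec"
  )
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("<channel_spec>\n")
  cat(sprintf(
    "  phi = %g, K = %s, N = %s, D = %g (1/2D = %g s), T = %s s\n",
    x$phi, paste(x$n_items, collapse = ","), paste(x$n_channels, collapse = ","),
    x$diffusivity, 1 / (2 * x$diffusivity), paste(x$duration, collapse = ",")
  ))
  invisible(x)
}

#' Pooled diffusivity under resource splitting
#'
#' When `N` units of resource are split across `K` networks, each network
#' keeps `N/K` of them and its diffusivity scales up accordingly:
#' `Dbar = D * K / N`.
#'
#' @param diffusivity Per-unit-resource diffusivity `D`, positive.
#' @param n_items Set size `K`.
#' @param n_channels Resource count `N`, positive.
#' @return The effective per-network diffusivity `D * K / N`.
#' @export
pooled_diffusivity <- function(diffusivity, n_items, n_channels) {
  if (any(diffusivity <= 0) || any(n_items <= 0) || any(n_channels <= 0)) {
    abort("`diffusivity`, `n_items` and `n_channels` must all be positive.")
  }
  diffusivity * n_items / n_channels
}

#' Direct-storage mean squared error
#'
#' Recall error of the direct-storage model: each of the `K` items diffuses
#' with the pooled diffusivity `D*K/N`, so in the unsaturated regime
#' `MSE = phi^2 * 2 * D * (K/N) * T` — linear in delay and set size, inverse
#' in channel count.
#'
#' @param spec A [channel_spec()].
#' @return Normalized mean squared error.
#' @export
#' @examples
#' direct_storage_mse(channel_spec(
#'   n_items = 2, n_channels = 4, diffusivity = 0.5, duration = 1
#' ))
direct_storage_mse <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  spec$phi^2 * 2 * spec$diffusivity * (spec$n_items / spec$n_channels) *
    spec$duration
}

#' Gaussian channel capacity
#'
#' Capacity of the scalar additive Gaussian channel, `(1/2) * log(1 + snr)`
#' in nats per channel use (natural logarithms throughout the package; bits
#' differ by a factor of `log(2)`).
#'
#' @param snr Signal-to-noise ratio, nonnegative.
#' @return Capacity in nats per use.
#' @export
gaussian_capacity <- function(snr) {
  if (any(snr < 0)) abort("`snr` must be nonnegative.")
  0.5 * log1p(snr)
}

#' Sum-rate bound for a subset of items
#'
#' Achievable total information rate for any subset of the `K` items when
#' item `k` carries average codeword power `powers[k]` (unit total power)
#' and each channel use adds Gaussian noise of variance `2*D*T`:
#' `(1/2) * log(1 + sum(P_k) / (2*D*T))` nats per use.
#'
#' @param powers Numeric vector of per-item powers, nonnegative, summing to
#'   at most 1.
#' @param subset Integer indices into `powers` (default all items).
#' @param diffusivity,duration Channel noise parameters; `duration > 0`.
#' @return Rate in nats per channel use.
#' @export
sum_rate_bound <- function(powers, subset = seq_along(powers), diffusivity,
                           duration) {
  if (any(powers < 0)) abort("powers must be nonnegative.")
  if (sum(powers) > 1 + 1e-12) abort("powers must sum to at most 1.")
  if (duration <= 0) abort("`duration` must be positive.")
  if (length(subset) > 0 &&
      (any(subset < 1) || any(subset > length(powers)))) {
    abort("`subset` indices out of range.")
  }
  gaussian_capacity(sum(powers[subset]) / (2 * diffusivity * duration))
}

#' Per-item information rate under equal allocation
#'
#' With power and rate split equally across the `K` items, each item's rate
#' per channel use is `(1/(2K)) * log(1 + 1/(2*D*T))`; over `N` channel uses
#' the item accumulates `N` times that, i.e. `(N/K)` times the Gaussian
#' capacity at `snr = 1/(2*D*T)`.
#'
#' @param spec A [channel_spec()] with `duration > 0`.
#' @return A tibble with columns `per_use_rate` and `total_rate` (nats).
#' @export
per_item_rate <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  if (any(spec$duration <= 0)) {
    abort("`duration` must be positive: the zero-delay channel is noiseless and its rate unbounded.")
  }
  per_use <- gaussian_capacity(spec$snr) / spec$n_items
  tibble(per_use_rate = per_use, total_rate = spec$n_channels * per_use)
}

#' Rate-distortion interval for a uniform source
#'
#' For a source uniform on `[0, phi]` conveyed at rate `R` nats, the
#' achievable mean squared reconstruction error is sandwiched between the
#' Shannon lower bound `phi^2 * exp(-2R) / (2*pi*e)` and the
#' uniform-quantization bound `phi^2 * exp(-2R) / 12`.
#'
#' @param rate Source rate in nats, nonnegative.
#' @param phi Source range (default 1).
#' @return A tibble with columns `lower` and `upper` (normalized units^2).
#' @export
rate_distortion_interval <- function(rate, phi = 1) {
  if (any(rate < 0)) abort("`rate` must be nonnegative.")
  tibble(
    lower = phi^2 * exp(-2 * rate) / (2 * pi * exp(1)),
    upper = phi^2 * exp(-2 * rate) / 12
  )
}

#' Coded-storage lower bound on mean squared error
#'
#' The information-theoretic floor on recall error for any encoder-decoder
#' pair around the diffusive storage stage:
#' `phi^2 / (2*pi*e) * (1 + 1/(2*D*T))^(-N/K)`.
#' Evaluated in the log domain for stability at large `N/K`.  The `T = 0`
#' limit is 0 by continuity (infinite SNR).
#'
#' @param spec A [channel_spec()].
#' @return Normalized mean squared error lower bound.
#' @export
#' @examples
#' coded_storage_mse_bound(channel_spec(
#'   n_items = 6, n_channels = 10, diffusivity = 1 / (2 * 2.28), duration = 3
#' ))
coded_storage_mse_bound <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  coded_mse_(spec$phi, spec$n_items, spec$n_channels, spec$diffusivity,
             spec$duration)
}

# vectorized cores, shared with the fitting grid
direct_mse_ <- function(phi, K, N, D, T) {
  phi^2 * 2 * D * (K / N) * T
}

coded_mse_ <- function(phi, K, N, D, T) {
  # at T = 0 the SNR is infinite and exp(-Inf) gives the 0 limit directly
  phi^2 / (2 * pi * exp(1)) * exp(-(N / K) * log1p(1 / (2 * D * T)))
}

#' Consistency of the capacity and variance-bound forms
#'
#' The heuristic route to the coded bound inserts the per-item information
#' `(N/K) * gaussian_capacity(snr)` into the variance floor `exp(-2*I)`;
#' this checks, to relative tolerance, that the result equals the closed
#' form `(1 + snr)^(-N/K)` used everywhere else.
#'
#' @param snr Signal-to-noise ratio, nonnegative.
#' @param n_channels,n_items `N` and `K`.
#' @param tol Relative tolerance (default `1e-12`).
#' @return `TRUE` if the two forms agree within `tol` for every input.
#' @export
heuristic_identity_check <- function(snr, n_channels, n_items, tol = 1e-12) {
  lhs <- exp(-2 * (n_channels / n_items) * gaussian_capacity(snr))
  rhs <- exp(-(n_channels / n_items) * log1p(snr))
  all(abs(lhs - rhs) <= tol * pmax(abs(rhs), .Machine$double.xmin))
}

#' Combined neural resource
#'
#' Both models price neural hardware by the same combination
#' `N * (1/(2*D))`, in seconds: it is proportional to the total neuron count
#' behind the memory channels, and it is the quantity the fit landscape's
#' valley trades off.
#'
#' @param n_channels `N`, positive.
#' @param inv2d `1/(2*D)` in seconds, positive.
#' @return Resource `N/(2*D)` in seconds.
#' @export
resource <- function(n_channels, inv2d) {
  if (any(n_channels <= 0) || any(inv2d <= 0)) {
    abort("`n_channels` and `inv2d` must be positive.")
  }
  n_channels * inv2d
}

#' Model curves over a design grid
#'
#' Tabulates either model's predicted normalized MSE over set sizes and
#' delays — the tabular equivalent of drawing the theory lines through a
#' performance plot.
#'
#' @param model `"direct"` or `"coded"`.
#' @param set_sizes,delays Vectors of `K` values and delays (s).
#' @param n_channels `N` (ignored by the direct model except through
#'   `rho`); for `"direct"` supply `rho = N/(2*D)` instead.
#' @param inv2d `1/(2*D)` in seconds (coded model).
#' @param rho `N/(2*D)` in seconds (direct model).
#' @param phi Variable range (default 1).
#' @return A tibble with columns `set_size`, `delay_s`, `mse_norm`.
#' @export
#' @examples
#' theory_curve("coded", set_sizes = c(1, 2, 4, 6), delays = c(0.1, 1, 2, 3),
#'              n_channels = 10, inv2d = 2.28)
theory_curve <- function(model = c("direct", "coded"), set_sizes, delays,
                         n_channels = NULL, inv2d = NULL, rho = NULL,
                         phi = 1) {
  model <- match.arg(model)
  grid <- tidyr::expand_grid(set_size = set_sizes, delay_s = delays)
  mse <- if (model == "direct") {
    if (is.null(rho)) abort("direct model needs `rho` = N/(2*D) in seconds.")
    phi^2 * grid$set_size * grid$delay_s / rho
  } else {
    if (is.null(n_channels) || is.null(inv2d)) {
      abort("coded model needs `n_channels` and `inv2d`.")
    }
    coded_mse_(phi, grid$set_size, n_channels, 1 / (2 * inv2d), grid$delay_s)
  }
  dplyr::mutate(grid, mse_norm = mse)
}
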