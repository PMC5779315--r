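# Monte-Carlo simulator of the storage channel: a stored circular variable
# drifting as a Brownian motion on the circle.  There is no restoring force:
# drift runs along the flat manifold of attractor states, so increments are
# plain Gaussians with variance 2*D*dt, accumulated and wrapped.

#' Configuration for the wrapped-diffusion simulator
#'
#' @param diffusivity Diffusivity `D` in (normalized range)^2 per second,
#'   nonnegative (`0` gives frozen paths — useful as a null check).
#' @param total_time Total simulated time in seconds.
#' @param dt Step size in seconds (default `total_time / 1000`).  Increments
#'   are exact Gaussians, so `dt` affects only the time resolution, not the
#'   law of the process; [simulate_diffusion()] with `exact = TRUE` skips
#'   stepping entirely.
#' @param n_paths Number of independent paths.
#' @param circumference Circular range `C` (default 1, the normalized
#'   180-degree range).
#' @param seed RNG seed; the same config and seed reproduce the ensemble
#'   exactly.
#' @return A `diffusion_config` list.
#' @export
diffusion_config <- function(diffusivity, total_time, dt = total_time / 1000,
                             n_paths = 1000L, circumference = 1, seed = NULL) {
  if (diffusivity < 0) abort("`diffusivity` must be nonnegative.")
  if (total_time <= 0) abort("`total_time` must be positive.")
  if (dt <= 0 || dt > total_time) abort("need 0 < dt <= total_time.")
  if (n_paths < 1) abort("`n_paths` must be at least 1.")
  if (circumference <= 0) abort("`circumference` must be positive.")
  structure(
    list(
      diffusivity = diffusivity, total_time = total_time, dt = dt,
      n_paths = as.integer(n_paths), circumference = circumference,
      seed = seed
    ),
    class = "diffusion_config"
  )
}

#' Simulate diffusive drift of a stored circular variable
#'
#' Accumulates i.i.d. Gaussian increments of variance `2*D*dt` along each
#' path and records the wrapped displacement at the requested times.  With
#' `exact = TRUE` each requested time is sampled in a single step of
#' variance `2*D*t` — the same law, cheaper for large ensembles (paths are
#' then independent across times rather than shared trajectories).
#'
#' @param config A [diffusion_config()].
#' @param sample_times Times (s) at which to record displacements; must lie
#'   in `(0, total_time]`.
#' @param exact Use the single-step exact sampler (default `FALSE`).
#' @return A tibble (`diffusion_ensemble`) with columns `time`, `path`,
#'   `displacement` — the signed wrapped displacement in `(-C/2, C/2]`.
#' @export
#' @examples
#' cfg <- diffusion_config(0.001, total_time = 2, n_paths = 200, seed = 1)
#' ens <- simulate_diffusion(cfg, sample_times = c(0.5, 1, 2))
#' dplyr::summarise(dplyr::group_by(ens, time),
#'                  msd = mean(displacement^2))
simulate_diffusion <- function(config, sample_times, exact = FALSE) {
  stopifnot(inherits(config, "diffusion_config"))
  sample_times <- sort(unique(sample_times))
  if (any(sample_times <= 0) || any(sample_times > config$total_time + 1e-12)) {
    abort("`sample_times` must lie in (0, total_time].")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  C <- config$circumference
  n <- config$n_paths
  if (exact) {
    disp <- lapply(sample_times, function(t) {
      wrap_displacement(rnorm(n, 0, sqrt(2 * config$diffusivity * t)), C)
    })
  } else {
    # march the shared trajectories, landing exactly on each sample time
    knots <- sort(unique(c(seq(0, config$total_time, by = config$dt),
                           sample_times)))
    knots <- knots[knots <= max(sample_times) + 1e-12]
    pos <- numeric(n)
    disp <- vector("list", length(sample_times))
    j <- 1L
    for (i in seq_along(knots)[-1]) {
      step <- knots[i] - knots[i - 1]
      pos <- pos + rnorm(n, 0, sqrt(2 * config$diffusivity * step))
      while (j <= length(sample_times) &&
             abs(knots[i] - sample_times[j]) < 1e-12) {
        disp[[j]] <- wrap_displacement(pos, C)
        j <- j + 1L
      }
    }
  }
  out <- tibble(
    time = rep(sample_times, each = n),
    path = rep(seq_len(n), times = length(sample_times)),
    displacement = unlist(disp)
  )
  class(out) <- c("diffusion_ensemble", class(out))
  attr(out, "circumference") <- C
  out
}

#' Mean squared displacement by time
#'
#' @param ensemble A [simulate_diffusion()] result.
#' @return A tibble with columns `time`, `msd` (mean squared wrapped
#'   displacement), `mc_se` (its Monte-Carlo standard error) and `n_paths`.
#' @export
ensemble_msd <- function(ensemble) {
  ensemble |>
    group_by(.data$time) |>
    summarise(
      msd = mean(.data$displacement^2),
      mc_se = sd(.data$displacement^2) / sqrt(dplyr::n()),
      n_paths = dplyr::n(),
      .groups = "drop"
    )
}

#' Estimate the diffusivity from an ensemble
#'
#' Regresses mean squared displacement through the origin on time and
#' returns half the slope — valid in the unsaturated regime where
#' `2*D*t` is small against `C^2` so wrapping is negligible.
#'
#' @param ensemble A [simulate_diffusion()] result (or any tibble with
#'   `time` and `displacement` columns) observed at two or more times.
#' @return The diffusivity estimate (normalized units^2 / s).
#' @export
estimate_diffusivity <- function(ensemble) {
  msd <- ensemble_msd(ensemble)
  if (nrow(msd) < 2) {
    abort("need at least two sample times to estimate a slope.")
  }
  slope <- sum(msd$time * msd$msd) / sum(msd$time^2)
  slope / 2
}

#' Simulate direct storage of K items under resource splitting
#'
#' Stores `K` items in `K` independent wrapped diffusions, each running at
#' the pooled diffusivity `D*K/N`, and reports each item's squared wrapped
#' error after the delay.  In the unsaturated regime the grand mean
#' converges to [direct_storage_mse()].
#'
#' @param n_items,n_channels `K` and `N`.
#' @param diffusivity Diffusivity `D`, nonnegative.
#' @param duration Delay `T` in seconds.
#' @param n_trials Number of simulated trials.
#' @param circumference Circular range (default 1).
#' @param seed RNG seed.
#' @return A tibble with columns `trial`, `item`, `sq_error` (normalized
#'   units^2).
#' @export
simulate_direct_storage <- function(n_items, n_channels, diffusivity,
                                    duration, n_trials = 1000L,
                                    circumference = 1, seed = NULL) {
  if (n_items < 1 || n_channels <= 0) abort("invalid `n_items`/`n_channels`.")
  if (diffusivity < 0 || duration < 0) {
    abort("`diffusivity` and `duration` must be nonnegative.")
  }
  if (!is.null(seed)) set.seed(seed)
  dbar <- if (diffusivity > 0) {
    pooled_diffusivity(diffusivity, n_items, n_channels)
  } else {
    0
  }
  k <- as.integer(n_items)
  err <- wrap_displacement(
    rnorm(n_trials * k, 0, sqrt(2 * dbar * duration)), circumference
  )
  tibble(
    trial = rep(seq_len(n_trials), each = k),
    item = rep(seq_len(k), times = n_trials),
    sq_error = err^2
  )
}
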