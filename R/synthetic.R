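# Synthetic delayed-estimation datasets.  The generator emulates a
# multi-item orientation recall experiment: oriented bars are shown, one is
# probed after a variable delay, and the subject dials in the remembered
# orientation.  Responses are the target plus wrapped-normal noise whose
# per-cell variance follows either theory curve anchored at the shortest
# delay, so every downstream stage (summaries, fits, model comparison) can
# be exercised without any external data.

#' Delayed-estimation experiment design
#'
#' Defaults emulate a standard design: 10 subjects; set sizes 1, 2, 4, 6;
#' delays 0.1, 1, 2, 3 s; each subject completes 11-15 blocks (drawn
#' uniformly per subject) of 80 trials, a block holding exactly 5 trials per
#' (set size, delay) cell; item colors are drawn from 8 distinguishable
#' colors.
#'
#' @param n_subjects Number of subjects.
#' @param set_sizes Item counts `K`.
#' @param delays Storage delays in seconds; the smallest is the anchoring
#'   baseline delay.
#' @param blocks_range Inclusive range of blocks per subject (length 2).
#' @param trials_per_cell_per_block Trials per (set size, delay) cell in
#'   each block.
#' @param n_colors Number of distinct item colors; must cover the largest
#'   set size.
#' @return An `experiment_design` list; `trials_per_block` is derived.
#' @export
experiment_design <- function(n_subjects = 10L,
                              set_sizes = c(1L, 2L, 4L, 6L),
                              delays = c(0.1, 1, 2, 3),
                              blocks_range = c(11L, 15L),
                              trials_per_cell_per_block = 5L,
                              n_colors = 8L) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (length(blocks_range) != 2 || blocks_range[1] > blocks_range[2]) {
    abort("`blocks_range` must be an increasing pair.")
  }
  if (n_colors < max(set_sizes)) {
    abort("`n_colors` must cover the largest set size.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      set_sizes = sort(as.integer(set_sizes)),
      delays = sort(delays),
      blocks_range = as.integer(blocks_range),
      trials_per_cell_per_block = as.integer(trials_per_cell_per_block),
      trials_per_block = length(set_sizes) * length(delays) *
        as.integer(trials_per_cell_per_block),
      n_colors = as.integer(n_colors)
    ),
    class = "experiment_design"
  )
}

#' Generative error model for synthetic trials
#'
#' Response noise is wrapped normal on the 180-degree circle.  The target
#' second moment of a (K, T) cell is
#' `baseline_mse[K] + D(K, T) - D(K, T0)` where `D` is the direct or coded
#' theory curve and `T0` the shortest delay, so generated data satisfy the
#' anchoring convention of the fitting stage by construction.  Per-subject
#' error scales are lognormal with spread `subject_scale_sd` on the log
#' scale (0 disables subject heterogeneity).
#'
#' @param kind `"coded"`, `"direct"`, or `"custom"` (a user-supplied MSE
#'   table).
#' @param baseline_mse Named numeric vector of normalized MSE at the
#'   shortest delay, one entry per set size.  Defaults span ~7-20 degrees
#'   RMS from 1 to 6 items.
#' @param n_channels,inv2d Coded-model parameters `N` and `1/(2*D)` in
#'   seconds.
#' @param rho Direct-model resource `N/(2*D)` in seconds.
#' @param mse_table For `kind = "custom"`: a tibble with columns
#'   `set_size`, `delay_s`, `mse_norm` giving `D(K, T)` directly.
#' @param subject_scale_sd Lognormal spread of per-subject error scale.
#' @param phi Variable range (default 1).
#' @return A `generative_model` list.
#' @export
generative_model <- function(kind = c("coded", "direct", "custom"),
                             baseline_mse = c(`1` = 0.0015, `2` = 0.003,
                                              `4` = 0.007, `6` = 0.012),
                             n_channels = 10, inv2d = 2.28, rho = 1215,
                             mse_table = NULL, subject_scale_sd = 0,
                             phi = 1) {
  kind <- match.arg(kind)
  if (any(baseline_mse < 0) || any(baseline_mse >= 0.25)) {
    abort("`baseline_mse` entries must lie in [0, 1/4).")
  }
  if (kind == "custom" && is.null(mse_table)) {
    abort("`kind = \"custom\"` needs `mse_table`.")
  }
  structure(
    list(
      kind = kind, baseline_mse = baseline_mse, n_channels = n_channels,
      inv2d = inv2d, rho = rho, mse_table = mse_table,
      subject_scale_sd = subject_scale_sd, phi = phi
    ),
    class = "generative_model"
  )
}

# model curve D(K, T) for one model kind, vectorized over K and T
model_mse_ <- function(model, set_size, delay_s) {
  switch(model$kind,
    direct = model$phi^2 * set_size * delay_s / model$rho,
    coded = coded_mse_(model$phi, set_size, model$n_channels,
                       1 / (2 * model$inv2d), delay_s),
    custom = {
      key <- paste(set_size, delay_s)
      tab <- model$mse_table
      idx <- match(key, paste(tab$set_size, tab$delay_s))
      if (anyNA(idx)) abort("`mse_table` is missing some (set_size, delay) cells.")
      tab$mse_norm[idx]
    }
  )
}

# Second moment of the wrapped displacement of N(0, sigma^2) on a circle of
# circumference C: E[wrap(eps)^2].  Approaches sigma^2 for small sigma and
# C^2/12 (the wrapped-uniform limit) as sigma grows.
wrapped_second_moment <- function(sigma, circumference = 1) {
  C <- circumference
  if (sigma <= 0) return(0)
  if (sigma > 5 * C) return(C^2 / 12)
  jmax <- ceiling((8 * sigma) / C) + 1
  f <- function(u) {
    dens <- 0
    for (j in -jmax:jmax) dens <- dens + dnorm(u + j * C, 0, sigma)
    u^2 * dens
  }
  integrate(f, -C / 2, C / 2, rel.tol = 1e-10)$value
}

# Invert wrapped_second_moment: the Gaussian sigma whose wrapped noise has
# the requested mean squared displacement.  Targets at or above C^2/12 are
# unreachable (the circle saturates); warn and fall back to the uniform
# limit.
sigma_for_mse <- function(target, circumference = 1) {
  C <- circumference
  if (target < 0) abort("target MSE must be nonnegative.")
  if (target == 0) return(0)
  if (target >= C^2 / 12 * (1 - 1e-9)) {
    warn(sprintf(
      "target cell MSE %.4g saturates the circular range (max %.4g for wrapped-normal noise); using the wrapped-uniform limit.",
      target, C^2 / 12
    ))
    return(10 * C)
  }
  uniroot(
    function(s) wrapped_second_moment(s, C) - target,
    lower = sqrt(target) / 2, upper = 5 * C, tol = 1e-12
  )$root
}

#' Generate a synthetic trial table
#'
#' Draws the full trial-level dataset for a design and generative model:
#' exact per-block cell counts, targets uniform on `[0, 180)` degrees,
#' responses equal to the target plus wrapped-normal noise whose second
#' moment matches the model's anchored cell variance.  Deterministic given
#' `seed`.
#'
#' @param design An [experiment_design()].
#' @param model A [generative_model()].
#' @param seed RNG seed.
#' @return A tibble of trials with columns `subject`, `block`, `trial`
#'   (0-based within block), `set_size`, `delay_s`, `target_deg`,
#'   `response_deg`, `color`.
#' @export
#' @examples
#' trials <- generate_dataset(
#'   experiment_design(n_subjects = 2, blocks_range = c(2, 2)),
#'   generative_model("coded", n_channels = 10, inv2d = 2.28),
#'   seed = 1
#' )
#' dplyr::count(trials, set_size, delay_s)
generate_dataset <- function(design, model, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(model, "generative_model"))
  if (!is.null(seed)) set.seed(seed)
  t0 <- min(design$delays)

  cells <- tidyr::expand_grid(set_size = design$set_sizes,
                              delay_s = design$delays)
  base <- model$baseline_mse[as.character(cells$set_size)]
  if (anyNA(base)) abort("`baseline_mse` must name every set size in the design.")
  cells$target_mse <- as.numeric(base) +
    model_mse_(model, cells$set_size, cells$delay_s) -
    model_mse_(model, cells$set_size, t0)

  subjects <- purrr::map(seq_len(design$n_subjects), function(s) {
    block_opts <- seq(design$blocks_range[1], design$blocks_range[2])
    n_blocks <- block_opts[sample.int(length(block_opts), 1L)]
    scale_s <- if (model$subject_scale_sd > 0) {
      exp(rnorm(1, 0, model$subject_scale_sd))
    } else {
      1
    }
    blocks <- purrr::map(seq_len(n_blocks), function(b) {
      tab <- cells[rep(seq_len(nrow(cells)),
                       each = design$trials_per_cell_per_block),
                   c("set_size", "delay_s", "target_mse")]
      tab <- tab[sample.int(nrow(tab)), ]        # randomized trial order
      tab$block <- b
      tab$trial <- seq_len(nrow(tab)) - 1L
      tab
    })
    out <- dplyr::bind_rows(blocks)
    out$subject <- s
    out$target_mse <- out$target_mse * scale_s
    out
  })
  trials <- dplyr::bind_rows(subjects)

  # one sigma solve per distinct target variance
  sig_map <- vapply(unique(trials$target_mse), sigma_for_mse, numeric(1))
  names(sig_map) <- format(unique(trials$target_mse), digits = 17)
  sigma <- sig_map[format(trials$target_mse, digits = 17)]

  n <- nrow(trials)
  target <- runif(n, 0, 1)                       # normalized orientation
  noise <- rnorm(n, 0, sigma)
  response <- (target + noise) %% 1

  trials |>
    mutate(
      target_deg = norm_to_deg(target),
      response_deg = norm_to_deg(response),
      color = sample.int(design$n_colors, n, replace = TRUE)
    ) |>
    select("subject", "block", "trial", "set_size", "delay_s",
           "target_deg", "response_deg", "color") |>
    arrange(.data$subject, .data$block, .data$trial)
}

trial_cols <- c("subject", "block", "trial", "set_size", "delay_s",
                "target_deg", "response_deg", "color")

#' Write and read trial tables
#'
#' Comma-separated files with header
#' `subject,block,trial,set_size,delay_s,target_deg,response_deg,color`;
#' angles written with 4 decimal places.  Reading validates every row:
#' angles must lie in `[0, 180)` and all fields must parse.
#'
#' @param trials A trial tibble as produced by [generate_dataset()].
#' @param path File path.
#' @return `read_trials()` returns the trial tibble; `write_trials()`
#'   returns `trials` invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing)) {
    abort(paste("trial table is missing columns:",
                paste(missing, collapse = ", ")))
  }
  out <- trials[trial_cols]
  out$target_deg <- sprintf("%.4f", out$target_deg)
  out$response_deg <- sprintf("%.4f", out$response_deg)
  readr::write_csv(out, path, progress = FALSE)
  invisible(trials)
}

#' @rdname write_trials
#' @param col_map Optional named character vector mapping this package's
#'   column names to the names used in the file (e.g.
#'   `c(set_size = "K", delay_s = "T")`), so external deposits with other
#'   headers can be ingested.
#' @export
read_trials <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        abort(sprintf("column `%s` (mapped to `%s`) not found in file.",
                      col_map[[std]], std))
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  missing <- setdiff(trial_cols, names(raw))
  if (length(missing)) {
    abort(paste("file is missing columns:", paste(missing, collapse = ", ")))
  }
  raw <- raw[trial_cols]
  if (nrow(raw) == 0) return(as_tibble(raw))
  for (col in c("target_deg", "response_deg")) {
    vals <- raw[[col]]
    bad <- which(!is.finite(vals) | vals < 0 | vals >= 180)
    if (length(bad)) {
      abort(sprintf("`%s` out of [0, 180) at row(s) %s.", col,
                    paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  num <- c("subject", "block", "trial", "set_size", "delay_s", "color")
  for (col in num) {
    if (!is.numeric(raw[[col]]) || anyNA(raw[[col]])) {
      abort(sprintf("column `%s` has malformed entries at row(s) %s.", col,
                    paste(utils::head(which(is.na(raw[[col]])), 5),
                          collapse = ", ")))
    }
  }
  as_tibble(raw)
}
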