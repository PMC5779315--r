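# From trials to the per-(set size, delay) performance summary the models
# are fitted to.  Errors are signed angular differences on the 180-degree
# circle, squared, normalized by 180^2, averaged within subject, then
# averaged across subjects; the SEM is taken across subjects so the error
# bars live on the same structure as the mean.

#' Signed circular error between target and response
#'
#' The signed angular difference on the 180-degree-periodic orientation
#' circle, in degrees on `(-90, 90]`.  Antisymmetric except at the
#' measure-zero boundary tie (a 90-degree error), which maps to `+90` for
#' determinism.
#'
#' @param target_deg,response_deg Orientations in degrees, in `[0, 180)`.
#' @return Signed error `response - target` wrapped to `(-90, 90]`.
#' @export
#' @examples
#' circular_error(179, 1)   # wraps to +2
circular_error <- function(target_deg, response_deg) {
  ok <- function(x) all(is.finite(x) & x >= 0 & x < 180)
  if (!ok(target_deg) || !ok(response_deg)) {
    abort("orientations must lie in [0, 180).")
  }
  wrap_displacement(response_deg - target_deg, circumference = 180)
}

#' Per-cell performance summary of a trial table
#'
#' For every (set size, delay) cell: the normalized mean squared error
#' (`mse_norm`), its SEM across participants (`sem_norm`), the pooled
#' per-trial variance of squared errors (`var_norm`, used as the
#' observation variance in the model-comparison likelihood), and counts.
#' `mse_norm` is the unweighted mean of per-subject mean squared errors, so
#' that it sits on the same structure as the across-subject SEM; set
#' `pooled = TRUE` for the trial-pooled alternative mean.
#'
#' @param trials A trial tibble ([generate_dataset()] / [read_trials()]).
#' @param pooled Use the trial-pooled mean instead of the mean of subject
#'   means (default `FALSE`).
#' @return A `performance_table`: a tibble with one row per cell and
#'   columns `set_size`, `delay_s`, `mse_norm`, `sem_norm`, `var_norm`,
#'   `n_trials`, `n_subjects`, carrying the baseline delay as attribute
#'   `baseline_delay`.  Cells observed in a single subject get `NA` SEM
#'   with a warning.
#' @export
performance_table <- function(trials, pooled = FALSE) {
  if (nrow(trials) == 0) abort("empty trial table.")
  sq <- trials |>
    mutate(sq_norm = deg_to_norm(
      circular_error(.data$target_deg, .data$response_deg)
    )^2)

  by_subject <- sq |>
    group_by(.data$set_size, .data$delay_s, .data$subject) |>
    summarise(subj_mse = mean(.data$sq_norm), n = dplyr::n(),
              .groups = "drop")

  tab <- by_subject |>
    group_by(.data$set_size, .data$delay_s) |>
    summarise(
      mse_subj = mean(.data$subj_mse),
      sem_norm = sd(.data$subj_mse) / sqrt(dplyr::n()),
      n_trials = sum(.data$n),
      n_subjects = dplyr::n(),
      .groups = "drop"
    )

  pooled_stats <- sq |>
    group_by(.data$set_size, .data$delay_s) |>
    summarise(mse_pooled = mean(.data$sq_norm),
              var_norm = var(.data$sq_norm), .groups = "drop")

  tab <- tab |>
    left_join(pooled_stats, by = c("set_size", "delay_s")) |>
    mutate(mse_norm = if (pooled) .data$mse_pooled else .data$mse_subj) |>
    select("set_size", "delay_s", "mse_norm", "sem_norm", "var_norm",
           "n_trials", "n_subjects") |>
    arrange(.data$set_size, .data$delay_s)

  if (any(tab$n_subjects < 2)) {
    warn("some cells have a single subject: SEM is undefined there.")
  }
  structure(tab,
            class = c("performance_table", class(tab)),
            baseline_delay = min(tab$delay_s))
}

#' @export
print.performance_table <- function(x, ...) {
  cat(sprintf("# performance_table: baseline delay %g s\n",
              attr(x, "baseline_delay")))
  NextMethod()
}

# baseline (shortest-delay) MSE per set size; fitting anchors curves here
baseline_mse_of <- function(table) {
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  base <- table[table$delay_s == t0, ]
  setNames(base$mse_norm, base$set_size)
}
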