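# Likelihood-based adjudication between the two models.  The observation
# is each trial's normalized squared error; its distribution within a
# (set size, delay) cell is taken as Gaussian with mean given by the
# model's anchored prediction and variance given by the empirical pooled
# per-trial variance of squared errors (shared by both models, so only the
# means differ).  The BIC penalty is k*log(2*pi*n) as used here; the
# conventional k*log(n) is available behind `penalty = "standard"`.

#' Pointwise Gaussian p-values of cell means against a model
#'
#' For each post-baseline cell, how likely the observed across-subject mean
#' is under a Gaussian centered on the model prediction with the cell's
#' SEM: `z = (mse - pred)/sem`, `p = 2*(1 - pnorm(|z|))`.
#'
#' @param table A [performance_table()].
#' @param predictions A tibble with columns `set_size`, `delay_s`, `pred`
#'   covering every post-baseline cell (e.g. a fit's `$predictions`).
#' @return A tibble with columns `set_size`, `delay_s`, `z`, `p`.  Cells
#'   with zero/undefined SEM get `NA` with a warning.
#' @export
point_pvalues <- function(table, predictions) {
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  cells <- table[table$delay_s > t0, ]
  joined <- dplyr::left_join(
    cells, predictions[c("set_size", "delay_s", "pred")],
    by = c("set_size", "delay_s")
  )
  if (anyNA(joined$pred)) {
    abort("`predictions` must cover every post-baseline cell.")
  }
  bad_sem <- !is.finite(joined$sem_norm) | joined$sem_norm <= 0
  if (any(bad_sem)) warn("cells with zero/undefined SEM get NA p-values.")
  z <- ifelse(bad_sem, NA_real_,
              (joined$mse_norm - joined$pred) / joined$sem_norm)
  tibble(set_size = joined$set_size, delay_s = joined$delay_s,
         z = z, p = 2 * (1 - pnorm(abs(z))))
}

#' Gaussian log-likelihood of trials under a model's predictions
#'
#' Sums, over every trial in a post-baseline cell, the log density of the
#' trial's normalized squared error under a Gaussian with the cell's model
#' prediction as mean and the cell's empirical pooled variance of squared
#' errors (`var_norm`) as variance.
#'
#' @param trials A trial tibble.
#' @param predictions A tibble with `set_size`, `delay_s`, `pred` covering
#'   the post-baseline cells.
#' @param table The [performance_table()] supplying `var_norm` per cell.
#' @return The log-likelihood, with the number of contributing trials as
#'   attribute `n_obs`.
#' @export
trial_log_likelihood <- function(trials, predictions, table) {
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  cells <- table[table$delay_s > t0,
                 c("set_size", "delay_s", "var_norm")]
  cells <- dplyr::left_join(
    cells, predictions[c("set_size", "delay_s", "pred")],
    by = c("set_size", "delay_s")
  )
  if (anyNA(cells$pred)) {
    abort("`predictions` must cover every post-baseline cell.")
  }
  if (any(!is.finite(cells$var_norm) | cells$var_norm <= 0)) {
    abort("every cell needs a positive empirical variance `var_norm`.")
  }
  obs <- trials |>
    mutate(sq_norm = deg_to_norm(
      circular_error(.data$target_deg, .data$response_deg)
    )^2) |>
    inner_join(cells, by = c("set_size", "delay_s"))
  ll <- sum(dnorm(obs$sq_norm, mean = obs$pred, sd = sqrt(obs$var_norm),
                  log = TRUE))
  structure(ll, n_obs = nrow(obs))
}

#' Bayesian Information Criterion
#'
#' `BIC = -2*loglik + k*log(2*pi*n)` with `penalty = "2pin"` (the default
#' convention here); `penalty = "standard"` uses the textbook `k*log(n)`.
#' Differences between models are unchanged by adding the same number of
#' parameters to both — the penalty shift cancels exactly.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Parameter count `k`.
#' @param n_obs Observation count `n`, at least 1.
#' @param penalty `"2pin"` or `"standard"`.
#' @return A `bic_report` list: `log_likelihood`, `n_params`, `n_obs`,
#'   `bic`, `penalty`.
#' @export
bic <- function(loglik, n_params, n_obs, penalty = c("2pin", "standard")) {
  penalty <- match.arg(penalty)
  if (n_obs < 1 || n_params < 0) abort("need n_obs >= 1 and n_params >= 0.")
  pen <- if (penalty == "2pin") log(2 * pi * n_obs) else log(n_obs)
  structure(
    list(log_likelihood = as.numeric(loglik), n_params = n_params,
         n_obs = n_obs, bic = -2 * as.numeric(loglik) + n_params * pen,
         penalty = penalty),
    class = "bic_report"
  )
}

#' @export
print.bic_report <- function(x, ...) {
  cat(sprintf("BIC = %.4f  (loglik = %.4f, k = %d, n = %d, penalty %s)\n",
              x$bic, x$log_likelihood, x$n_params, x$n_obs, x$penalty))
  invisible(x)
}

#' Compare the direct and coded models on one dataset
#'
#' Assembles both models' trial log-likelihoods (same observations, same
#' empirical cell variances), their BICs (`k = 1` direct, `k = 2` coded by
#' default; `count_baselines` adds the 4 anchored baseline values to both,
#' which leaves the difference unchanged), the difference
#' `delta_bic = BIC(direct) - BIC(coded)` — positive favors the coded
#' model — and each model's pointwise p-values.
#'
#' @param trials The trial tibble both fits were derived from.
#' @param direct_fit A [fit_direct()] result.
#' @param coded_fit A [fit_coded()] result.
#' @param table Optional [performance_table()]; recomputed from `trials`
#'   when omitted.
#' @param n_obs Override for the BIC's `n` (e.g. a per-cell count); default
#'   is the total number of observations entering the likelihood.
#' @param count_baselines Add 4 baseline parameters to each model's count.
#' @param penalty Passed to [bic()].
#' @return An `stm_comparison` list: `bic_direct`, `bic_coded`,
#'   `delta_bic`, and a `pvalues` tibble with one row per cell and model.
#' @export
compare_models <- function(trials, direct_fit, coded_fit, table = NULL,
                           n_obs = NULL, count_baselines = FALSE,
                           penalty = c("2pin", "standard")) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(direct_fit, "direct_fit"),
            inherits(coded_fit, "coded_fit"))
  table <- table %||% performance_table(trials)
  same_cells <- identical(
    direct_fit$predictions[c("set_size", "delay_s")],
    coded_fit$predictions[c("set_size", "delay_s")]
  )
  if (!same_cells) abort("the two fits cover different (set size, delay) cells.")

  ll_d <- trial_log_likelihood(trials, direct_fit$predictions, table)
  ll_c <- trial_log_likelihood(trials, coded_fit$predictions, table)
  n <- n_obs %||% attr(ll_d, "n_obs")
  extra <- if (count_baselines) 4L else 0L
  bic_d <- bic(ll_d, 1L + extra, n, penalty)
  bic_c <- bic(ll_c, 2L + extra, n, penalty)

  pv <- dplyr::bind_rows(
    mutate(point_pvalues(table, direct_fit$predictions), model = "direct"),
    mutate(point_pvalues(table, coded_fit$predictions), model = "coded")
  )
  structure(
    list(bic_direct = bic_d, bic_coded = bic_c,
         delta_bic = bic_d$bic - bic_c$bic, pvalues = pv),
    class = "stm_comparison"
  )
}

#' @export
print.stm_comparison <- function(x, ...) {
  cat("<model comparison: direct vs coded storage>\n")
  cat(sprintf("  BIC direct = %.2f (k = %d)\n", x$bic_direct$bic,
              x$bic_direct$n_params))
  cat(sprintf("  BIC coded  = %.2f (k = %d)\n", x$bic_coded$bic,
              x$bic_coded$n_params))
  cat(sprintf("  delta BIC  = %.2f (positive favors coded storage)\n",
              x$delta_bic))
  invisible(x)
}
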