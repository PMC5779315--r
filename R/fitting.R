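# Anchored weighted-least-squares fitting.  Both theory curves are anchored
# to the empirical shortest-delay (baseline) error of each set size:
# predicted MSE(K, T) = data MSE(K, T0) + D(K, T) - D(K, T0).  The baseline
# cells therefore contribute zero residual and are excluded from the loss;
# the remaining cells are weighted by the inverse of their across-subject
# SEM (squared residuals multiplied by 1/SEM; the conventional 1/SEM^2
# variant is available via `weight = "inv_var"`).

fit_weights_ <- function(table, weight, sem_floor) {
  fitted_cells <- table$delay_s > (attr(table, "baseline_delay") %||%
                                     min(table$delay_s))
  sem <- table$sem_norm
  if (weight == "ols") return(rep(1, nrow(table)))
  bad <- fitted_cells & (!is.finite(sem) | sem <= 0)
  if (any(bad) && is.null(sem_floor)) {
    abort(paste(
      "some fitted cells have zero or undefined SEM;",
      "supply `sem_floor` (a small pseudocount added to the SEMs) to proceed."
    ))
  }
  if (!is.null(sem_floor)) sem <- pmax(sem, sem_floor)
  switch(weight, inv_sem = 1 / sem, inv_var = 1 / sem^2)
}

# anchored model curve over the table's cells, vectorized
predict_cells_ <- function(table, model_kind, params, phi = 1) {
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  base <- baseline_mse_of(table)
  if (!all(as.character(table$set_size) %in% names(base))) {
    abort("every set size needs a baseline (shortest-delay) cell.")
  }
  d_of <- function(T) {
    if (model_kind == "direct") {
      phi^2 * table$set_size * T / params$rho
    } else {
      coded_mse_(phi, table$set_size, params$n_channels,
                 1 / (2 * params$inv2d), T)
    }
  }
  # grouping guarantees the baseline cells get exactly zero increment
  as.numeric(base[as.character(table$set_size)]) +
    (d_of(table$delay_s) - d_of(t0))
}

#' Anchored model prediction for cells of a performance table
#'
#' Evaluates `data MSE(K, T0) + D(K, T) - D(K, T0)` for the chosen model,
#' where `T0` is the table's baseline delay.  At `T = T0` the prediction is
#' the empirical baseline exactly.
#'
#' @param table A [performance_table()].
#' @param model_kind `"direct"` or `"coded"`.
#' @param params For `"direct"`: `list(rho = N/(2*D))` in seconds; for
#'   `"coded"`: `list(n_channels = N, inv2d = 1/(2*D))`.
#' @param set_size,delay_s Optional scalar cell; if omitted, predictions
#'   are returned for every cell of the table.
#' @param phi Variable range (default 1).
#' @return A tibble with columns `set_size`, `delay_s`, `pred` (or a single
#'   number when a cell is named).
#' @export
anchored_prediction <- function(table, model_kind = c("direct", "coded"),
                                params, set_size = NULL, delay_s = NULL,
                                phi = 1) {
  model_kind <- match.arg(model_kind)
  preds <- tibble(set_size = table$set_size, delay_s = table$delay_s,
                  pred = predict_cells_(table, model_kind, params, phi))
  if (is.null(set_size)) return(preds)
  hit <- preds$set_size == set_size & preds$delay_s == delay_s
  if (!any(hit)) abort("requested (set_size, delay) cell not in the table.")
  preds$pred[hit]
}

finish_fit_ <- function(table, model_kind, params, w, weight, phi, cls) {
  pred <- predict_cells_(table, model_kind, params, phi)
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  fitted_cells <- table$delay_s > t0
  resid <- table$mse_norm - pred
  wsse <- sum(w[fitted_cells] * resid[fitted_cells]^2)
  predictions <- tibble(
    set_size = table$set_size, delay_s = table$delay_s,
    mse_norm = table$mse_norm, sem_norm = table$sem_norm,
    pred = pred, residual = resid,
    weight = ifelse(fitted_cells, w, 0)
  )
  structure(
    c(params,
      list(wsse = wsse, predictions = predictions, weight_kind = weight,
           phi = phi, table = table)),
    class = c(cls, "stm_fit")
  )
}

#' Fit the direct-storage model
#'
#' One free parameter, the resource `rho = N/(2*D)` in seconds.  Anchored
#' residuals are linear in `1/rho`, so the weighted-least-squares minimizer
#' has a closed form; it is computed exactly (no iteration).
#'
#' @param table A [performance_table()] with at least two delays per set
#'   size.
#' @param weight Weighting of squared residuals: `"inv_sem"` (`1/SEM`, the
#'   default), `"inv_var"` (`1/SEM^2`), or `"ols"` (unit weights).
#' @param sem_floor Optional lower floor applied to SEMs before weighting;
#'   required if any fitted cell has zero SEM.
#' @param phi Variable range (default 1).
#' @return A `direct_fit` object: `rho` (s), `wsse`, and a `predictions`
#'   tibble with anchored predictions, residuals and weights per cell.
#' @export
fit_direct <- function(table, weight = c("inv_sem", "inv_var", "ols"),
                       sem_floor = NULL, phi = 1) {
  weight <- match.arg(weight)
  w <- fit_weights_(table, weight, sem_floor)
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  fit_idx <- table$delay_s > t0
  if (!any(fit_idx)) abort("table needs delays beyond the baseline delay.")
  base <- baseline_mse_of(table)
  # residual = a + theta * b with theta = 2D/N = 1/rho
  a <- as.numeric(base[as.character(table$set_size[fit_idx])]) -
    table$mse_norm[fit_idx]
  b <- phi^2 * table$set_size[fit_idx] * (table$delay_s[fit_idx] - t0)
  wf <- w[fit_idx]
  theta <- -sum(wf * a * b) / sum(wf * b^2)
  if (!is.finite(theta) || theta <= 0) {
    abort("weighted least squares gives a non-positive slope; the data do not grow with delay under this weighting.")
  }
  finish_fit_(table, "direct", list(rho = 1 / theta), w, weight, phi,
              "direct_fit")
}

#' Fit the direct model to the largest set size only, by OLS
#'
#' The single-curve variant: ordinary (unit-weight) least squares on the
#' `set_size == 6` cells alone (or the largest set size present), with
#' predictions still produced for every cell — useful for exposing how a
#' steep large-K curve over-predicts errors at small K.
#'
#' @inheritParams fit_direct
#' @param set_size The set size to fit on (default 6).
#' @return A `direct_fit` object.
#' @export
fit_direct_6item_ols <- function(table, set_size = 6, phi = 1) {
  if (!set_size %in% table$set_size) {
    abort(sprintf("set size %g not present in the table.", set_size))
  }
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  sub <- table$set_size == set_size & table$delay_s > t0
  if (!any(sub)) abort("no post-baseline cells at the requested set size.")
  base <- baseline_mse_of(table)
  a <- as.numeric(base[as.character(table$set_size[sub])]) -
    table$mse_norm[sub]
  b <- phi^2 * table$set_size[sub] * (table$delay_s[sub] - t0)
  theta <- -sum(a * b) / sum(b^2)
  if (!is.finite(theta) || theta <= 0) {
    abort("ordinary least squares gives a non-positive slope on this curve.")
  }
  w <- rep(1, nrow(table))
  w[table$set_size != set_size] <- 0      # only the chosen curve is scored
  finish_fit_(table, "direct", list(rho = 1 / theta), w, "ols", phi,
              "direct_fit")
}

# weighted SSE of the coded model over a (N, inv2d) grid: rows index N,
# columns index inv2d
coded_wsse_grid_ <- function(table, w, n_grid, inv2d_grid, phi) {
  t0 <- attr(table, "baseline_delay") %||% min(table$delay_s)
  fit_idx <- which(table$delay_s > t0)
  base <- baseline_mse_of(table)
  pref <- phi^2 / (2 * pi * exp(1))
  wsse <- matrix(0, length(n_grid), length(inv2d_grid))
  for (i in fit_idx) {
    K <- table$set_size[i]
    # (1 + inv2d/T)^(-N/K) via exp(-outer(N/K, log1p(inv2d/T)))
    d_t <- pref * exp(-outer(n_grid / K, log1p(inv2d_grid / table$delay_s[i])))
    d_t0 <- pref * exp(-outer(n_grid / K, log1p(inv2d_grid / t0)))
    resid <- base[[as.character(K)]] + d_t - d_t0 - table$mse_norm[i]
    wsse <- wsse + w[i] * resid^2
  }
  wsse[!is.finite(wsse)] <- Inf
  wsse
}

#' Fit the coded-storage bound over a parameter landscape
#'
#' Two free parameters: the channel count `N` and the per-channel inverse
#' diffusivity `1/(2*D)` in seconds.  The weighted SSE is evaluated on a
#' full (log-spaced by default) grid; the global grid argmin is refined by
#' local optimization in log-parameter space.  The per-`N` column minima
#' trace the landscape's valley, along which the combined resource
#' `N/(2*D)` is reported.
#'
#' @inheritParams fit_direct
#' @param n_grid Grid of `N` values (default 200 log-spaced points on
#'   `[1, 1000]`).
#' @param inv2d_grid Grid of `1/(2*D)` values in seconds (default 200
#'   log-spaced points on `[0.01, 1000]`).
#' @param refine Refine the grid argmin with Nelder-Mead in log space
#'   (default `TRUE`).
#' @return A `coded_fit` object: `n_channels`, `inv2d`, `resource`
#'   (`N/(2*D)`, s), `wsse`, `predictions`, plus the landscape as `surface`
#'   (long tibble `n_channels`, `inv2d`, `wsse`) and `valley` (per-`N` best
#'   `inv2d` with its `wsse` and `resource`).  Ties in the argmin resolve
#'   to the smallest `N`, then the smallest `inv2d`.
#' @export
fit_coded <- function(table, n_grid = logspace(1, 1e3, 200),
                      inv2d_grid = logspace(1e-2, 1e3, 200),
                      weight = c("inv_sem", "inv_var", "ols"),
                      sem_floor = NULL, refine = TRUE, phi = 1) {
  weight <- match.arg(weight)
  if (!length(n_grid) || !length(inv2d_grid)) abort("grids must be nonempty.")
  n_grid <- sort(n_grid)
  inv2d_grid <- sort(inv2d_grid)
  w <- fit_weights_(table, weight, sem_floor)
  wsse <- coded_wsse_grid_(table, w, n_grid, inv2d_grid, phi)
  if (all(!is.finite(wsse))) abort("no finite weighted SSE on the grid.")

  # lexicographic tie-break: smallest N, then smallest inv2d
  hits <- which(wsse == min(wsse), arr.ind = TRUE)
  best <- hits[order(hits[, 1], hits[, 2])[1], ]
  par <- c(n = n_grid[best[1]], inv2d = inv2d_grid[best[2]])

  obj <- function(logp) {
    p <- exp(logp)
    m <- coded_wsse_grid_(table, w, p[1], p[2], phi)[1, 1]
    if (!is.finite(m)) 1e300 else m
  }
  if (refine) {
    opt <- optim(log(par), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    par <- exp(opt$par)
  }

  valley_idx <- apply(wsse, 1, which.min)     # ties: which.min takes first
  valley <- tibble(
    n_channels = n_grid,
    inv2d = inv2d_grid[valley_idx],
    wsse = wsse[cbind(seq_along(n_grid), valley_idx)],
    resource = n_grid * inv2d_grid[valley_idx]
  )
  surface <- tibble(
    n_channels = rep(n_grid, times = length(inv2d_grid)),
    inv2d = rep(inv2d_grid, each = length(n_grid)),
    wsse = as.vector(wsse)
  )
  class(surface) <- c("error_surface", class(surface))

  fit <- finish_fit_(
    table, "coded",
    list(n_channels = unname(par[1]), inv2d = unname(par[2]),
         resource = unname(par[1] * par[2])),
    w, weight, phi, "coded_fit"
  )
  fit$surface <- surface
  fit$valley <- valley
  fit
}

#' @export
print.stm_fit <- function(x, ...) {
  kind <- if (inherits(x, "coded_fit")) "coded-storage bound" else "direct storage"
  cat(sprintf("<%s fit>\n", kind))
  if (inherits(x, "coded_fit")) {
    cat(sprintf("  N = %.4g, 1/2D = %.4g s, resource N/2D = %.4g s\n",
                x$n_channels, x$inv2d, x$resource))
  } else {
    cat(sprintf("  rho = N/2D = %.4g s\n", x$rho))
  }
  cat(sprintf("  weighted SSE = %.6g (%s weights)\n", x$wsse, x$weight_kind))
  invisible(x)
}

#' Leave-one-subject-out refits
#'
#' Rebuilds the performance table without each subject in turn, refits the
#' chosen model, and summarises the spread of the refitted parameters with
#' the jackknife standard error.
#'
#' @param trials A trial tibble with at least 3 subjects.
#' @param model_kind `"direct"` or `"coded"`.
#' @param ... Passed to [fit_direct()] / [fit_coded()] (grids, weights...).
#' @return A list with `estimates` (a tibble, one row per left-out subject)
#'   and `se` (named jackknife standard errors).
#' @export
jackknife_fits <- function(trials, model_kind = c("direct", "coded"), ...) {
  model_kind <- match.arg(model_kind)
  subjects <- sort(unique(trials$subject))
  if (length(subjects) < 3) abort("jackknife needs at least 3 subjects.")
  full_cells <- dplyr::distinct(trials, .data$set_size, .data$delay_s)

  rows <- purrr::map(subjects, function(s) {
    rest <- trials[trials$subject != s, ]
    left_cells <- dplyr::distinct(rest, .data$set_size, .data$delay_s)
    if (nrow(left_cells) < nrow(full_cells)) {
      abort(sprintf("removing subject %s empties a (set size, delay) cell.", s))
    }
    tab <- performance_table(rest)
    if (model_kind == "direct") {
      f <- fit_direct(tab, ...)
      tibble(subject_left_out = s, rho = f$rho, wsse = f$wsse)
    } else {
      f <- fit_coded(tab, ...)
      tibble(subject_left_out = s, n_channels = f$n_channels,
             inv2d = f$inv2d, resource = f$resource, wsse = f$wsse)
    }
  })
  estimates <- dplyr::bind_rows(rows)

  params <- setdiff(names(estimates), c("subject_left_out", "wsse"))
  n <- length(subjects)
  se <- vapply(params, function(p) {
    x <- estimates[[p]]
    sqrt((n - 1) / n * sum((x - mean(x))^2))
  }, numeric(1))
  list(estimates = estimates, se = se)
}
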