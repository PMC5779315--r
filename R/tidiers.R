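# broom-style accessors for fitted objects.

#' Tidy a direct-storage fit
#'
#' @param x A `direct_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.direct_fit <- function(x, ...) {
  tibble(term = "rho", estimate = x$rho)
}

#' @rdname tidy.direct_fit
#' @export
glance.direct_fit <- function(x, ...) {
  tibble(rho = x$rho, wsse = x$wsse, weight = x$weight_kind,
         n_cells = sum(x$predictions$weight > 0))
}

#' Tidy a coded-storage fit
#'
#' @param x A `coded_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.coded_fit <- function(x, ...) {
  tibble(term = c("n_channels", "inv2d", "resource"),
         estimate = c(x$n_channels, x$inv2d, x$resource))
}

#' @rdname tidy.coded_fit
#' @export
glance.coded_fit <- function(x, ...) {
  tibble(n_channels = x$n_channels, inv2d = x$inv2d, resource = x$resource,
         wsse = x$wsse, weight = x$weight_kind,
         n_cells = sum(x$predictions$weight > 0))
}

#' Tidy a model comparison
#'
#' @param x An `stm_comparison` object.
#' @param ... Unused.
#' @return One row per model with log-likelihood, parameter count and BIC.
#' @export
tidy.stm_comparison <- function(x, ...) {
  tibble(
    model = c("direct", "coded"),
    log_likelihood = c(x$bic_direct$log_likelihood,
                       x$bic_coded$log_likelihood),
    n_params = c(x$bic_direct$n_params, x$bic_coded$n_params),
    bic = c(x$bic_direct$bic, x$bic_coded$bic)
  )
}

#' @rdname tidy.stm_comparison
#' @export
glance.stm_comparison <- function(x, ...) {
  tibble(delta_bic = x$delta_bic, n_obs = x$bic_direct$n_obs,
         penalty = x$bic_direct$penalty)
}
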