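# Shared numeric helpers.  The whole package works in normalized units:
# the stored variable lives on a circle of circumference 1 (the full
# 180-degree orientation range), so squared errors are dimensionless and
# bounded by 1/4 (a maximal 90-degree error).

#' Wrap displacements onto a circle
#'
#' Maps values to the signed half-open interval `(-C/2, C/2]` on a circle of
#' circumference `C`.  The boundary tie at exactly `C/2` resolves to `+C/2`
#' for determinism.
#'
#' @param x Numeric vector of displacements (any real values).
#' @param circumference Circle circumference `C` (default 1, the normalized
#'   180-degree range).
#' @return Numeric vector in `(-C/2, C/2]`.
#' @export
#' @examples
#' wrap_displacement(c(0.6, -0.5, 0.5))
wrap_displacement <- function(x, circumference = 1) {
  stopifnot(circumference > 0)
  half <- circumference / 2
  # 90 - ((90 - d) mod 180) pattern: lands in (-half, half] with +half ties
  half - ((half - x) %% circumference)
}

#' Convert between degrees and normalized units
#'
#' The orientation range is 180 degrees; normalized units divide by 180 so
#' the variable lives on `[0, 1)` and squared errors on `[0, 1/4]`.
#'
#' @param deg,x Values in degrees / normalized units.
#' @return The converted values.
#' @export
deg_to_norm <- function(deg) deg / 180

#' @rdname deg_to_norm
#' @export
norm_to_deg <- function(x) x * 180

#' @rdname deg_to_norm
#' @param deg2,x2 Squared values in degrees^2 / normalized units^2.
#' @export
deg2_to_norm2 <- function(deg2) deg2 / 180^2

#' @rdname deg_to_norm
#' @export
norm2_to_deg2 <- function(x2) x2 * 180^2

#' Log-spaced grid
#'
#' `length.out` points geometrically spaced between `from` and `to`; used
#' for the `(N, 1/(2*D))` fit landscape.
#'
#' @param from,to Positive endpoints.
#' @param length.out Number of points.
#' @return Numeric vector.
#' @export
logspace <- function(from, to, length.out) {
  stopifnot(from > 0, to > 0, length.out >= 1)
  exp(seq(log(from), log(to), length.out = length.out))
}

# draw a seed for a sub-stream from the current RNG, keeping it a valid
# 32-bit integer
draw_seed <- function() sample.int(.Machine$integer.max, 1L)
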