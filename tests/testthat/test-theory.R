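# Closed-form theory: the direct-storage MSE, the coded-storage bound, and
# the information-theoretic pieces they are assembled from.

test_that("direct-storage MSE follows the pooled-diffusivity growth law", {
  spec <- channel_spec(n_items = 2, n_channels = 4, diffusivity = 0.5,
                       duration = 1)
  expect_equal(direct_storage_mse(spec), 0.5)   # 1 * 2*0.5 * (2/4) * 1

  zero <- channel_spec(n_items = 3, n_channels = 7, diffusivity = 0.2,
                       duration = 0)
  expect_identical(direct_storage_mse(zero), 0)

  # linear in T, linear in K, inverse in N, invariant under (cK, cN)
  base <- channel_spec(n_items = 2, n_channels = 5, diffusivity = 0.1,
                       duration = 1.3)
  expect_equal(
    direct_storage_mse(channel_spec(n_items = 2, n_channels = 5,
                                    diffusivity = 0.1, duration = 2.6)),
    2 * direct_storage_mse(base)
  )
  expect_equal(
    direct_storage_mse(channel_spec(n_items = 6, n_channels = 15,
                                    diffusivity = 0.1, duration = 1.3)),
    direct_storage_mse(base)
  )
  expect_error(channel_spec(n_items = 1, n_channels = 0, diffusivity = 1,
                            duration = 1), "positive")
  expect_error(channel_spec(n_items = 1, n_channels = 1, diffusivity = -1,
                            duration = 1), "positive")
})

test_that("pooled diffusivity splits resource across items", {
  expect_equal(pooled_diffusivity(0.7, 5, 5), 0.7)     # identity split
  expect_equal(pooled_diffusivity(1, 2, 4), 0.5)
  d_small_n <- pooled_diffusivity(1, 2, 4)
  d_large_n <- pooled_diffusivity(1, 2, 8)
  expect_true(d_large_n < d_small_n)
  expect_error(pooled_diffusivity(1, 2, 0), "positive")
})

test_that("Gaussian capacity is the half-log law in nats", {
  expect_identical(gaussian_capacity(0), 0)
  expect_equal(gaussian_capacity(exp(2) - 1), 1)
  snr <- seq(0, 20, by = 0.5)
  cap <- gaussian_capacity(snr)
  expect_true(all(diff(cap) > 0))          # strictly increasing
  expect_true(all(diff(diff(cap)) < 0))    # concave
  expect_error(gaussian_capacity(-0.1), "nonnegative")
})

test_that("sum-rate bound reduces to capacity on the full set", {
  p <- rep(1 / 4, 4)
  expect_equal(sum_rate_bound(p, integer(0), diffusivity = 1, duration = 1), 0)
  expect_equal(sum_rate_bound(rep(0, 4), 1:4, diffusivity = 1, duration = 1), 0)
  # full set, unit power, 2DT = 1 -> (1/2) ln 2
  expect_equal(sum_rate_bound(p, 1:4, diffusivity = 0.5, duration = 1),
               0.5 * log(2))
  expect_equal(sum_rate_bound(p, 1:4, diffusivity = 0.5, duration = 1),
               gaussian_capacity(1))
  expect_error(sum_rate_bound(p, 5, diffusivity = 1, duration = 1),
               "out of range")
})

test_that("per-item rate carries N/K of the single-channel capacity", {
  one <- channel_spec(n_items = 1, n_channels = 1, diffusivity = 0.25,
                      duration = 2)
  expect_equal(per_item_rate(one)$per_use_rate, gaussian_capacity(one$snr))

  # doubling K halves the per-item rate
  k2 <- channel_spec(n_items = 2, n_channels = 1, diffusivity = 0.25,
                     duration = 2)
  expect_equal(per_item_rate(k2)$per_use_rate,
               per_item_rate(one)$per_use_rate / 2)

  # frozen high-precision value: 1/2D = 3 s, T = 3 s, K = N = 6 -> ln(2)/2
  spec <- channel_spec(n_items = 6, n_channels = 6, diffusivity = 1 / 6,
                       duration = 3)
  expect_equal(per_item_rate(spec)$total_rate, 0.346573590279972654709,
               tolerance = 1e-12)
  expect_error(
    per_item_rate(channel_spec(n_items = 1, n_channels = 1,
                               diffusivity = 1, duration = 0)),
    "unbounded"
  )
})

test_that("rate-distortion interval has the uniform-source endpoints", {
  r0 <- rate_distortion_interval(0)
  expect_equal(r0$lower, 1 / (2 * pi * exp(1)))
  expect_equal(r0$upper, 1 / 12)
  r1 <- rate_distortion_interval(1)
  expect_equal(r1$lower, r0$lower * exp(-2))
  expect_equal(r1$upper, r0$upper * exp(-2))
  rates <- seq(0, 10, by = 0.25)
  rd <- rate_distortion_interval(rates, phi = 2)
  expect_true(all(rd$lower < rd$upper))    # 2*pi*e > 12
  expect_error(rate_distortion_interval(-1), "nonnegative")
})

test_that("coded bound matches its frozen high-precision value and limits", {
  # phi = 1, 1/2D = 3 s, T = 3 s, N = K = 6: snr = 1 -> 1/(4*pi*e)
  spec <- channel_spec(n_items = 6, n_channels = 6, diffusivity = 1 / 6,
                       duration = 3)
  expect_equal(coded_storage_mse_bound(spec), 0.0292749157621595803451,
               tolerance = 1e-12)

  # long-delay limit: zero SNR ceiling phi^2/(2*pi*e)
  long <- channel_spec(n_items = 2, n_channels = 4, diffusivity = 1,
                       duration = 1e12)
  expect_equal(coded_storage_mse_bound(long), 1 / (2 * pi * exp(1)),
               tolerance = 1e-9)

  # T = 0 limit defined as 0 by continuity
  t0 <- channel_spec(n_items = 2, n_channels = 4, diffusivity = 1,
                     duration = 0)
  expect_identical(coded_storage_mse_bound(t0), 0)
})

test_that("coded bound is monotone in N, T, K and capped by the zero-rate floor", {
  grid <- tidyr::expand_grid(K = c(1, 2, 4, 6), N = c(1, 5, 20, 100),
                             T = c(0.1, 1, 3), D = c(0.05, 0.2))
  v <- function(K, N, T, D) {
    coded_storage_mse_bound(channel_spec(n_items = K, n_channels = N,
                                         diffusivity = D, duration = T))
  }
  vals <- purrr::pmap_dbl(grid, function(K, N, T, D) v(K, N, T, D))
  expect_true(all(vals <= 1 / (2 * pi * exp(1)) + 1e-15))
  eps <- 1e-6
  up_n <- purrr::pmap_dbl(grid, function(K, N, T, D) v(K, N * (1 + eps), T, D))
  up_t <- purrr::pmap_dbl(grid, function(K, N, T, D) v(K, N, T * (1 + eps), D))
  up_k <- purrr::pmap_dbl(grid, function(K, N, T, D) v(K * (1 + eps), N, T, D))
  expect_true(all(up_n < vals))
  expect_true(all(up_t > vals))
  expect_true(all(up_k > vals))
})

test_that("bound composes exactly from rate then rate-distortion", {
  # the closed-form coded bound must equal the rate-distortion lower
  # endpoint at the per-item total rate, across a 1296-point parameter grid
  grid <- tidyr::expand_grid(
    K = c(1, 2, 4, 6), N = logspace(1, 1e3, 6),
    T = c(0.1, 0.5, 1, 2, 3, 10), D = logspace(1e-3, 10, 9)
  )
  expect_gte(nrow(grid), 1000)
  direct_form <- purrr::pmap_dbl(grid, function(K, N, T, D) {
    coded_storage_mse_bound(channel_spec(n_items = K, n_channels = N,
                                         diffusivity = D, duration = T))
  })
  composed <- purrr::pmap_dbl(grid, function(K, N, T, D) {
    spec <- channel_spec(n_items = K, n_channels = N, diffusivity = D,
                         duration = T)
    rate_distortion_interval(per_item_rate(spec)$total_rate)$lower
  })
  expect_true(all(
    abs(direct_form - composed) <=
      1e-12 * pmax(composed, .Machine$double.xmin)
  ))
})

test_that("capacity/variance-bound identity holds and log-domain form is stable", {
  expect_true(heuristic_identity_check(0, 10, 2))
  expect_true(heuristic_identity_check(1, 4, 2))    # both sides 1/4
  expect_equal(exp(-2 * 2 * gaussian_capacity(1)), 0.25)
  snr <- runif(200, 0, 100)
  expect_true(heuristic_identity_check(snr, 17, 3))

  # log-domain evaluation agrees with naive powering where the latter is finite
  naive <- function(phi, K, N, D, T) {
    phi^2 / (2 * pi * exp(1)) * (1 + 1 / (2 * D * T))^(-N / K)
  }
  grid <- tidyr::expand_grid(K = c(1, 6), N = c(1, 50, 400),
                             T = c(0.1, 3), D = c(0.01, 1))
  for (i in seq_len(nrow(grid))) {
    nv <- naive(1, grid$K[i], grid$N[i], grid$D[i], grid$T[i])
    if (is.finite(nv) && nv > 0) {
      spec <- channel_spec(n_items = grid$K[i], n_channels = grid$N[i],
                           diffusivity = grid$D[i], duration = grid$T[i])
      expect_equal(coded_storage_mse_bound(spec), nv, tolerance = 1e-12)
    }
  }
})

test_that("resource is the N times 1/2D product with its trade-off invariance", {
  expect_equal(resource(5, 6.4), 32)
  expect_equal(resource(1, 7.3), 7.3)
  expect_equal(resource(3 * 10, 4.5 / 3), resource(10, 4.5))
  expect_error(resource(-1, 1), "positive")
})

test_that("theory_curve tabulates both models over a design grid", {
  tc <- theory_curve("direct", set_sizes = c(1, 6), delays = c(1, 2),
                     rho = 100)
  expect_equal(tc$mse_norm, c(1 / 100, 2 / 100, 6 / 100, 12 / 100))
  cc <- theory_curve("coded", set_sizes = 6, delays = 3,
                     n_channels = 6, inv2d = 3)
  expect_equal(cc$mse_norm, 0.0292749157621595803451, tolerance = 1e-12)
})
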