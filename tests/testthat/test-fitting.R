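# Anchored WLS fitting: exact anchoring, closed-form/numeric agreement,
# landscape search, and jackknife refits.

test_that("anchored predictions hit the empirical baselines to machine precision", {
  tab <- noiseless_table("coded", n_channels = 10, inv2d = 2.28)
  for (kind in c("direct", "coded")) {
    params <- if (kind == "direct") list(rho = 300) else {
      list(n_channels = 7, inv2d = 1.5)
    }
    preds <- anchored_prediction(tab, kind, params)
    at_t0 <- preds$delay_s == 0.1
    expect_identical(preds$pred[at_t0], tab$mse_norm[at_t0])
  }
  # direct increment is the closed-form slope term
  p <- anchored_prediction(tab, "direct", list(rho = 250),
                           set_size = 4, delay_s = 2)
  base <- tab$mse_norm[tab$set_size == 4 & tab$delay_s == 0.1]
  expect_equal(p, base + 4 * (2 - 0.1) / 250)
  expect_error(
    anchored_prediction(tab, "direct", list(rho = 250),
                        set_size = 3, delay_s = 2),
    "not in the table"
  )
})

test_that("direct fit recovers a noiseless table exactly and matches a numeric optimizer", {
  tab <- noiseless_table("direct", rho = 100)
  fit <- fit_direct(tab)
  expect_equal(fit$rho, 100, tolerance = 1e-10)
  expect_equal(fit$wsse, 0, tolerance = 1e-16)

  # dual oracle: closed form vs bounded scalar optimizer on noisy tables
  set.seed(55)
  for (i in 1:5) {
    tab2 <- noiseless_table("direct", rho = 10^runif(1, 1, 3))
    tab2$mse_norm <- tab2$mse_norm * exp(rnorm(nrow(tab2), 0, 0.05))
    tab2$sem_norm <- tab2$sem_norm * exp(rnorm(nrow(tab2), 0, 0.3))
    fit2 <- fit_direct(tab2)
    obj <- function(log_rho) {
      p <- anchored_prediction(tab2, "direct", list(rho = exp(log_rho)))
      post <- tab2$delay_s > 0.1
      sum((1 / tab2$sem_norm[post]) *
            (p$pred[post] - tab2$mse_norm[post])^2)
    }
    num <- optimize(obj, c(log(1), log(1e6)), tol = 1e-12)
    expect_equal(fit2$rho, exp(num$minimum), tolerance = 1e-6)
  }
})

test_that("WLS argmin is invariant to a global SEM rescale but not to the weight kind", {
  tab <- noiseless_table("direct", rho = 480)
  set.seed(60)
  tab$mse_norm <- tab$mse_norm * exp(rnorm(nrow(tab), 0, 0.1))
  tab$sem_norm <- abs(rnorm(nrow(tab), 1e-4, 3e-5))
  scaled <- tab
  scaled$sem_norm <- scaled$sem_norm * 7
  expect_equal(fit_direct(tab)$rho, fit_direct(scaled)$rho,
               tolerance = 1e-12)
  # unit-weight OLS equals WLS when all SEMs are equal
  flat <- tab
  flat$sem_norm <- rep(2e-4, nrow(flat))
  expect_equal(fit_direct(flat)$rho, fit_direct(flat, weight = "ols")$rho,
               tolerance = 1e-12)

  # zero SEM: refuse unless a floor is supplied
  zero <- tab
  zero$sem_norm[zero$set_size == 2 & zero$delay_s == 2] <- 0
  expect_error(fit_direct(zero), "sem_floor")
  expect_no_error(fit_direct(zero, sem_floor = 1e-6))
})

test_that("coded fit finds the generating parameters of a noiseless table", {
  tab <- noiseless_table("coded", n_channels = 10, inv2d = 2.28)
  fit <- fit_coded(tab, n_grid = logspace(1, 100, 120),
                   inv2d_grid = logspace(0.05, 100, 120))
  expect_lt(abs(fit$n_channels - 10) / 10, 0.01)
  expect_lt(abs(fit$inv2d - 2.28) / 2.28, 0.01)
  expect_equal(fit$resource, fit$n_channels * fit$inv2d)

  # the valley passes through the truth: at the grid N nearest 10 the
  # column minimum sits near inv2d = 2.28
  near <- fit$valley[which.min(abs(fit$valley$n_channels - 10)), ]
  expect_lt(abs(near$inv2d - 2.28) / 2.28, 0.15)

  # grid+refine argmin agrees with a finer brute-force grid: it can beat
  # the grid's best cell but not sit more than a couple of cells away
  # (the valley is nearly flat along the resource direction)
  fine_n <- logspace(5, 20, 200)
  fine_i <- logspace(1, 5, 200)
  brute <- fit_coded(tab, fine_n, fine_i, refine = FALSE)
  step_n <- fine_n[2] / fine_n[1]
  step_i <- fine_i[2] / fine_i[1]
  expect_lte(fit$wsse, brute$wsse + 1e-15)
  expect_lt(abs(log(fit$n_channels / brute$n_channels)), 2 * log(step_n))
  expect_lt(abs(log(fit$inv2d / brute$inv2d)), 2 * log(step_i))
})

test_that("the error surface is invariant to grid order and tie-breaks are lexicographic", {
  tab <- noiseless_table("coded", n_channels = 8, inv2d = 3)
  g_n <- logspace(2, 50, 40)
  g_i <- logspace(0.2, 20, 40)
  a <- fit_coded(tab, g_n, g_i, refine = FALSE)
  b <- fit_coded(tab, sample(g_n), sample(g_i), refine = FALSE)
  expect_equal(a$surface$wsse, b$surface$wsse)
  expect_equal(a$n_channels, b$n_channels)
})

test_that("the six-item OLS variant reproduces the full fit on exact direct data", {
  tab <- noiseless_table("direct", rho = 800)
  full <- fit_direct(tab)
  six <- fit_direct_6item_ols(tab)
  expect_equal(six$rho, full$rho, tolerance = 1e-10)
  expect_equal(nrow(six$predictions), nrow(tab))   # predictions for all K

  # when the 6-item curve is steeper than the shared-resource law allows,
  # fitting it alone over-predicts the low-K errors
  steep <- tab
  six_cells <- steep$set_size == 6 & steep$delay_s > 0.1
  steep$mse_norm[six_cells] <- steep$mse_norm[six_cells] +
    3 * 6 * (steep$delay_s[six_cells] - 0.1) / 800
  biased <- fit_direct_6item_ols(steep)
  low_k <- biased$predictions$set_size == 1 & biased$predictions$delay_s > 0.1
  expect_true(all(biased$predictions$pred[low_k] >
                    steep$mse_norm[low_k]))
})

test_that("jackknife spread collapses for identical subjects and tracks noise", {
  one <- generate_dataset(
    experiment_design(n_subjects = 1, blocks_range = c(2L, 2L)),
    generative_model("direct", rho = 1215), seed = 90
  )
  clones <- dplyr::bind_rows(
    lapply(1:4, function(s) dplyr::mutate(one, subject = s))
  )
  jk <- jackknife_fits(clones, "direct", weight = "ols")
  expect_equal(nrow(jk$estimates), 4)
  expect_equal(unname(jk$se["rho"]), 0, tolerance = 1e-8)

  trials <- generate_dataset(experiment_design(),
                             generative_model("direct", rho = 1215),
                             seed = 91)
  jk2 <- jackknife_fits(trials, "direct")
  expect_gt(jk2$se["rho"], 0)
  expect_true(all(abs(log(jk2$estimates$rho / 1215)) < log(2)))
  expect_error(jackknife_fits(one, "direct"), "3 subjects")
})
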