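# minimal hand-built fit for closed-form prediction checks
mk_fit <- function(beta, data, offset_log_total = 0, theta = 0.5, radius = NA_real_) {
  covs <- setdiff(names(beta), "(Intercept)")
  structure(
    list(beta = beta[c("(Intercept)", covs)], theta = theta, theta_se = NA_real_,
         se = beta * NA, vcov = NULL, deviance = NA_real_, df = nrow(data) - length(beta),
         n = nrow(data), loglik = NA_real_, aic = NA_real_,
         offset_log_total = offset_log_total, covariates = covs,
         fitted = NULL, radius = radius, data = data, iterations = 0L),
    class = "nb2_fit"
  )
}

test_that("predictions evaluate the published-style coefficient arithmetic exactly", {
  beta <- c("(Intercept)" = -8.025, road = 0.545, slope = 0.002,
            edge = -0.355, soil = 0.022)
  data <- tibble::tibble(road = c(0, 2), slope = c(0, 50), edge = c(0, 1.2),
                         soil = c(0, 185), count = c(0L, 1L))
  fit <- mk_fit(beta, data, offset_log_total = log(4911))
  new <- tibble::tibble(road = 1, slope = 20, edge = 0.5, soil = 100)
  pred <- predict_units(fit, new)
  # independent arithmetic: exp(-8.025 + 0.545 + 0.04 - 0.1775 + 2.2)
  expect_equal(pred$.pred, exp(-5.4175), tolerance = 1e-12)
  expect_lt(pred$.pred, 1)  # relative-frequency scale

  # all covariates zero -> exp(intercept); count scale multiplies by T
  zero <- tibble::tibble(road = 0, slope = 0, edge = 0, soil = 0)
  expect_equal(predict_units(fit, zero)$.pred, exp(-8.025), tolerance = 1e-12)
  expect_equal(predict_units(fit, zero, scale = "count")$.pred,
               4911 * exp(-8.025), tolerance = 1e-12)
})

test_that("prediction invariants: duplicates, ordering, rescaling", {
  u <- mk_units_1d(200, seed = 300)
  uu <- simulate_counts(u, beta = c("(Intercept)" = 0.5, x = 1.2), theta = 0.8,
                        total_fixes = 1, seed = 301)
  fit <- fit_nb2(uu, "x")
  new <- tibble::tibble(x = c(0.3, 0.7, 0.3, 0.9))
  p <- predict_units(fit, new)
  expect_equal(p$.pred[1], p$.pred[3])                     # identical covariates
  p_rev <- predict_units(fit, new[4:1, ])
  expect_equal(p_rev$.pred, rev(p$.pred))                   # order never matters

  pm <- predict_units(fit, new, rescale = "max1")
  expect_equal(max(pm$.pred), 1)
  ps <- predict_units(fit, new, rescale = "unit_sum")
  expect_true(all(ps$.pred >= 0))
  expect_equal(sum(ps$.pred), 1, tolerance = 1e-12)
})

test_that("predictions are invariant to recentering a covariate (with refit)", {
  u <- mk_units_1d(300, seed = 302)
  uu <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1.5), theta = 0.6,
                        total_fixes = 1, seed = 303)
  f0 <- fit_nb2(uu, "x")
  uc <- uu; uc$x <- uc$x - mean(uc$x)
  fc <- fit_nb2(uc, "x")
  new <- tibble::tibble(x = seq(0.1, 0.9, by = 0.1))
  newc <- tibble::tibble(x = new$x - mean(uu$x))
  expect_equal(predict_units(f0, new)$.pred, predict_units(fc, newc)$.pred,
               tolerance = 1e-6)
})

test_that("prediction guards: unknown covariates, radius mismatch, extrapolation warning", {
  u <- mk_units_1d(100, seed = 304)
  uu <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1), theta = 1,
                        total_fixes = 1, seed = 305)
  fit <- fit_nb2(uu, "x")
  expect_error(predict_units(fit, tibble::tibble(z = 1)), "unknown covariate")
  bad_r <- tibble::tibble(x = 0.5, radius = 999)
  expect_error(predict_units(fit, bad_r), "radius mismatch")
  expect_warning(predict_units(fit, tibble::tibble(x = 2)), "outside the modeled range")
})

test_that("marginal profiles are flat for null covariates and monotone for positive ones", {
  data <- withr::with_seed(309,
    tibble::tibble(a = runif(50), b = runif(50), count = rpois(50, 5)))
  pf <- mk_fit(c("(Intercept)" = -2, a = 0, b = 1), data)
  reps <- tibble::tibble(
    `(Intercept)` = withr::with_seed(310, -2 + rnorm(30, 0, 0.1)),
    a = rep(0, 30),      # null covariate in every replicate
    b = rep(1, 30)       # strictly positive coefficient in every replicate
  )
  boot <- structure(list(point_fit = pf, replicates = reps, level = 0.90,
                         B = 30, n_failed = 0, m = 5), class = "nb_bootstrap")
  flat <- marginal_profile(boot, "a", n_grid = 20)
  expect_lt(diff(range(flat$median)), 1e-12)
  expect_true(all(flat$lower <= flat$median & flat$median <= flat$upper))

  mono <- marginal_profile(boot, "b", n_grid = 20)
  expect_true(all(diff(mono$median) > 0))
  # joint max-1 scaling: the global maximum sits at the top of the range
  expect_equal(max(mono$upper), 1)
  expect_equal(which.max(mono$upper), 20)
  expect_error(marginal_profile(boot, "zz"), "not in the fitted model")
})

test_that("bootstrap envelopes contain the true marginal response in a well-specified world", {
  w <- smooth_world()
  sim <- simulate_locations(w$spec, seed = 12)
  bt <- suppressWarnings(bootstrap_by_animal(sim$locations, w$units,
                                             names(w$spec$surfaces), B = 200, seed = 13))
  for (cv in names(w$spec$beta)) {
    prof <- marginal_profile(bt, cv, n_grid = 40)
    truth <- exp(w$spec$beta[[cv]] * prof$value)
    # anchor the (scale-free) true curve to the median at mid-range
    truth <- truth * prof$median[20] / truth[20]
    expect_gte(mean(prof$lower <= truth & truth <= prof$upper), 0.85)
  }
})

test_that("prediction surfaces track the true intensity and respect rescaling", {
  grid <- withr::with_seed(300, {
    gr <- expand.grid(center_x = seq(25, 2975, by = 50),
                      center_y = seq(25, 2975, by = 50))
    tibble::tibble(unit_id = as.character(seq_len(nrow(gr))),
                   center_x = gr$center_x, center_y = gr$center_y, radius = 100,
                   a = gr$center_x / 3000, b = sin(2 * pi * gr$center_y / 1500))
  })
  train <- withr::with_seed(301, grid[sample.int(nrow(grid), 500), ])
  beta <- c("(Intercept)" = 1, a = 1.2, b = -0.7)
  train <- simulate_counts(train, beta, theta = 0.8, total_fixes = 1, seed = 302)
  fit <- fit_nb2(train, c("a", "b"))

  surf <- suppressWarnings(prediction_surface(fit, grid))
  true_intensity <- exp(1 + 1.2 * grid$a - 0.7 * grid$b)
  expect_gte(cor(surf$.pred, true_intensity, method = "spearman"), 0.9)

  # uniform covariates: constant surface; unit_sum gives 1/n everywhere
  flat_grid <- dplyr::mutate(grid[1:100, ], a = 0.5, b = 0)
  fs <- suppressWarnings(prediction_surface(fit, flat_grid, rescale = "unit_sum"))
  expect_equal(fs$.pred, rep(1 / 100, 100), tolerance = 1e-12)
  fm <- suppressWarnings(prediction_surface(fit, grid, rescale = "max1"))
  expect_equal(max(fm$.pred), 1)

  # autoplot returns a ggplot without evaluation errors
  expect_s3_class(autoplot(fm), "ggplot")
})
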