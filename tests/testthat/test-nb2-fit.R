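test_that("ML fit recovers simulated coefficients and agrees with an independent implementation", {
  u <- mk_units_1d(500)
  u <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1.5), theta = 0.5,
                       total_fixes = 1, seed = 2)
  fit <- fit_nb2(u, "x")

  # truth within 3 reported SEs
  expect_lt(abs(fit$beta[["(Intercept)"]] - 1), 3 * fit$se[["(Intercept)"]])
  expect_lt(abs(fit$beta[["x"]] - 1.5), 3 * fit$se[["x"]])

  # independent route: MASS's NB2 fitter on the same data
  skip_if_not_installed("MASS")
  m <- MASS::glm.nb(count ~ x, data = u)
  expect_equal(unname(fit$beta), unname(stats::coef(m)), tolerance = 1e-6)
  expect_equal(fit$theta, m$theta, tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(m)))), tolerance = 1e-5)
  expect_equal(fit$deviance, m$deviance, tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-8)
})

test_that("increasing the offset shifts only the intercept, exactly", {
  u <- mk_units_1d(400, seed = 101)
  u <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1.2), theta = 0.7,
                       total_fixes = 1, seed = 3)
  f1 <- fit_nb2(u, "x", offset_log_total = log(100))
  f2 <- fit_nb2(u, "x", offset_log_total = log(100) + log(10))
  expect_equal(f1$beta[["(Intercept)"]] - f2$beta[["(Intercept)"]], log(10),
               tolerance = 1e-8)
  expect_equal(f1$beta[["x"]], f2$beta[["x"]], tolerance = 1e-8)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
})

test_that("Poisson-generated counts drive theta to the equidispersed limit", {
  u <- mk_units_1d(500, seed = 102)
  u <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1.5), theta = Inf,
                       total_fixes = 1, seed = 4)
  fit <- fit_nb2(u, "x")
  expect_gt(fit$theta, 10 * mean(u$count))
  pois <- stats::glm(count ~ x, data = u, family = stats::poisson())
  expect_equal(unname(fit$beta), unname(stats::coef(pois)), tolerance = 1e-3)
})

test_that("the optimum dominates the truth and the deviance is well-behaved", {
  u <- mk_units_1d(300, seed = 103)
  truth <- c(1, 1.5)
  u <- simulate_counts(u, beta = c("(Intercept)" = truth[1], x = truth[2]),
                       theta = 0.5, total_fixes = 1, seed = 5)
  fit <- fit_nb2(u, "x")
  # ML definition: fitted log-likelihood >= log-likelihood at the truth
  ll_truth <- nbrsf:::nb2_loglik(u$count, exp(truth[1] + truth[2] * u$x), 0.5)
  expect_gte(fit$loglik, ll_truth)
  expect_gte(fit$deviance, 0)

  # a perfectly log-linear response gives an (essentially) saturated fit
  sat <- tibble::tibble(unit_id = as.character(1:5), center_x = 0, center_y = 0,
                        radius = 1, x = log(1:5), count = 1:5)
  sfit <- fit_nb2(sat, "x")
  expect_lt(gof_deviance_ratio(sfit), 1e-6)
  expect_equal(unname(sfit$fitted), as.numeric(1:5), tolerance = 1e-4)
})

test_that("fit validation rejects impossible inputs with informative errors", {
  u <- mk_units_1d(50, seed = 104)
  expect_error(fit_nb2(u, "x"), "no count column")
  u$count <- rep(0L, 50)
  expect_error(fit_nb2(u, "x"), "cannot estimate dispersion")
  u$count <- rep(c(0L, 3L), 25)
  expect_error(fit_nb2(u, "missing_cov"), "unknown covariate")
  u2 <- u; u2$x2 <- 2 * u2$x
  expect_error(fit_nb2(u2, c("x", "x2")), "rank-deficient")
  u3 <- u; u3$count <- u3$count + 0.5
  expect_error(fit_nb2(u3, "x"), "non-negative integers")
  expect_error(fit_nb2(u[1:2, ], "x"), "p \\+ 2")
})

test_that("deviance ratio is near one for well-specified counts and above one for panel data", {
  u <- mk_units_1d(500, seed = 105)
  uu <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1.5), theta = 0.5,
                        total_fixes = 1, seed = 6)
  ratio <- gof_deviance_ratio(fit_nb2(uu, "x"))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.3)

  # per-animal slope heterogeneity + unmodeled patchiness inflate D/df
  sp <- panel_spec()
  units0 <- panel_units()
  above <- sapply(1:20, function(s) {
    sim <- simulate_locations(sp, seed = 4000 + s)
    up <- count_locations(units0, sim$locations)
    gof_deviance_ratio(fit_nb2(up, "g", offset_log_total = log(nrow(sim$locations)))) > 1
  })
  expect_gte(mean(above), 0.8)
})

test_that("Wald intervals from the ML covariance have near-nominal coverage when well-specified", {
  u <- mk_units_1d(400, seed = 200)
  z <- qnorm(0.95)
  covered <- t(sapply(1:300, function(s) {
    uu <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1.5), theta = 0.5,
                          total_fixes = 1, seed = 1e4 + s)
    f <- fit_nb2(uu, "x")
    abs(f$beta - c(1, 1.5)) <= z * f$se
  }))
  expect_gt(mean(covered[, 1]), 0.85)
  expect_lt(mean(covered[, 1]), 0.96)
  expect_gt(mean(covered[, 2]), 0.85)
  expect_lt(mean(covered[, 2]), 0.96)
})

test_that("expected zero proportion matches the pmf and the observed zero fraction", {
  u <- mk_units_1d(500, seed = 106)
  uu <- simulate_counts(u, beta = c("(Intercept)" = 1, x = 1.5), theta = 0.5,
                        total_fixes = 1, seed = 7)
  fit <- fit_nb2(uu, "x")
  # independent arithmetic on the fitted means
  want <- mean((fit$theta / (fit$theta + fit$fitted))^fit$theta)
  expect_equal(expected_zero_proportion(fit), want, tolerance = 1e-12)
  # and it tracks the observed zero fraction within Monte-Carlo error
  expect_lt(abs(expected_zero_proportion(fit) - mean(uu$count == 0)), 0.03)
})

test_that("tidy and glance expose the fit in standard tabular form", {
  u <- mk_units_1d(300, seed = 107)
  uu <- simulate_counts(u, beta = c("(Intercept)" = 0.5, x = 1), theta = 1,
                        total_fixes = 1, seed = 8)
  fit <- fit_nb2(uu, "x", offset_log_total = log(300))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, c("(Intercept)", "x"))
  gl <- glance(fit)
  expect_equal(gl$df, 298)
  expect_equal(gl$deviance_ratio, gof_deviance_ratio(fit))
  expect_equal(gl$AIC, -2 * fit$loglik + 2 * 3)
})
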