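#' Fit the NB2 resource-selection regression by maximum likelihood
#'
#' Fits the log-link NB2 model `Y_i ~ NB2(u_i, theta)` with
#' `log(u_i) = offset_log_total + beta_0 + sum_j beta_j x_ji` to per-unit
#' location counts. With the offset set to `log(T)` — the log of the total
#' number of recorded fixes `T` — the systematic part models the *relative
#' frequency* of use of each unit, so `exp(beta_0 + sum beta_j x_j)` is an
#' estimate of the probability that any one recorded fix falls in a unit with
#' those covariates: a resource selection probability function.
#'
#' Estimation alternates (a) iteratively reweighted least squares for `beta`
#' at fixed `theta` with (b) one-dimensional profile maximum likelihood for
#' `theta` (on the log scale, enforcing positivity), until the joint
#' log-likelihood changes by less than `1e-8`; at convergence this is full
#' joint ML. Starting values are the Poisson-regression coefficients and a
#' method-of-moments dispersion.
#'
#' The reported covariance (`vcov`) is the inverse Fisher information for
#' `beta` at the optimum. These ML standard errors assume independent counts;
#' with panel (per-animal clustered) telemetry data they are anti-conservative,
#' and [bootstrap_by_animal()] is the endorsed inference path.
#'
#' @param units A unit table with a `count` column (see [count_locations()])
#'   and one numeric column per covariate.
#' @param covariates Character vector of covariate column names entering the
#'   linear predictor.
#' @param offset_log_total `log(T)` where `T` is the total number of recorded
#'   locations, or `NULL` (treated as 0) for a raw-count model.
#'
#' @return An object of class `nb2_fit`: a list with elements `beta`
#'   (named coefficient vector, intercept first), `theta` (ML dispersion),
#'   `se` (ML standard errors), `vcov`, `deviance`, `df` (`n - (p + 1)`),
#'   `loglik`, `aic`, `offset_log_total`, `fitted` (fitted means on the count
#'   scale), `data` (the modeling rows), and bookkeeping fields. Methods:
#'   [tidy()], [glance()], `print()`, `predict()` (see [predict_units()]).
#' @seealso [gof_deviance_ratio()], [expected_zero_proportion()],
#'   [bootstrap_by_animal()]
#' @examples
#' set.seed(1)
#' u <- tibble::tibble(unit_id = as.character(1:300), center_x = 0, center_y = 0,
#'                     radius = 100, x = runif(300))
#' u <- simulate_counts(u, beta = c("(Intercept)" = 0.5, x = 1), theta = 0.8,
#'                      total_fixes = 1, seed = 2)
#' fit <- fit_nb2(u, "x")
#' tidy(fit)
#' @export
fit_nb2 <- function(units, covariates, offset_log_total = NULL) {
  if (!"count" %in% names(units)) {
    abort("unit table has no count column; run count_locations() first",
          class = "nbrsf_fit_error")
  }
  y <- units$count
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y))) {
    abort("counts must be non-negative integers", class = "nbrsf_fit_error")
  }
  missing_cov <- setdiff(covariates, names(units))
  if (length(missing_cov)) {
    abort(paste0("unknown covariate column(s): ", paste(missing_cov, collapse = ", ")),
          class = "nbrsf_fit_error")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(units[covariates]))
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) {
    abort("covariates contain missing or non-finite values", class = "nbrsf_fit_error")
  }
  n <- nrow(X); p1 <- ncol(X)
  if (n < p1 + 1L) {
    abort("need at least p + 2 units to fit p covariates", class = "nbrsf_fit_error")
  }
  if (qr(X)$rank < p1) {
    abort("rank-deficient design: covariates are collinear", class = "nbrsf_fit_error")
  }
  if (all(y == 0)) {
    abort("all counts are zero: cannot estimate dispersion", class = "nbrsf_fit_error")
  }
  off <- if (is.null(offset_log_total)) 0 else as.numeric(offset_log_total)
  stopifnot(length(off) == 1L, is.finite(off))
  offv <- rep(off, n)

  fit <- nb2_ml(y, X, offv)

  se <- sqrt(diag(fit$vcov))
  mu <- fit$mu
  dev_terms <- ifelse(y > 0, y * log(y / mu), 0) -
    (y + fit$theta) * log((y + fit$theta) / (mu + fit$theta))
  deviance <- 2 * sum(dev_terms)

  structure(
    list(
      beta = fit$beta,
      theta = fit$theta,
      theta_se = fit$theta_se,
      se = setNames(se, names(fit$beta)),
      vcov = fit$vcov,
      deviance = deviance,
      df = n - p1,
      n = n,
      loglik = fit$loglik,
      aic = -2 * fit$loglik + 2 * (p1 + 1),
      offset_log_total = off,
      covariates = covariates,
      fitted = mu,
      radius = if ("radius" %in% names(units)) units$radius[1] else NA_real_,
      data = tibble::as_tibble(units[, c(covariates, "count")]),
      iterations = fit$iterations
    ),
    class = "nb2_fit"
  )
}

# alternating ML: IRLS for beta | theta, profile optimize for theta | beta
nb2_ml <- function(y, X, offv, max_outer = 100L, tol = 1e-8) {
  # Poisson start for beta
  beta <- suppressWarnings(
    glm.fit(X, y, family = poisson(), offset = offv)$coefficients
  )
  if (any(!is.finite(beta))) {
    abort("could not compute Poisson starting values", class = "nbrsf_fit_error")
  }
  ybar <- mean(y); s2 <- stats::var(y)
  theta <- if (is.finite(s2) && s2 > ybar) max(0.01, ybar^2 / (s2 - ybar)) else 100

  ll_beta <- function(beta, theta) {
    nb2_loglik(y, pmax(exp(pmin(drop(X %*% beta) + offv, 700)), 1e-300), theta)
  }

  irls <- function(beta, theta) {
    cur_ll <- ll_beta(beta, theta)
    for (i in 1:50) {
      eta <- drop(X %*% beta) + offv
      # floor mu: with extreme starting values exp(eta) can underflow to 0,
      # which would put NaN into the working response
      mu <- pmax(exp(pmin(eta, 700)), 1e-10)
      w <- mu / (1 + mu / theta)
      z <- (eta - offv) + (y - mu) / mu
      new_beta <- lm.wfit(X, z, w)$coefficients
      if (any(!is.finite(new_beta))) {
        abort("IRLS produced non-finite coefficients", class = "nbrsf_fit_error")
      }
      # step-halve: the raw IRLS step is not guaranteed uphill far from the
      # optimum, and overshooting makes the outer alternation oscillate
      new_ll <- ll_beta(new_beta, theta)
      halvings <- 0L
      while (new_ll < cur_ll - 1e-12 && halvings < 30L) {
        new_beta <- (new_beta + beta) / 2
        new_ll <- ll_beta(new_beta, theta)
        halvings <- halvings + 1L
      }
      if (new_ll < cur_ll - 1e-12) break  # no uphill step found; keep beta
      delta <- max(abs(new_beta - beta))
      beta <- new_beta
      cur_ll <- new_ll
      if (delta < 1e-11) break
    }
    beta
  }

  mu_of <- function(beta) exp(pmin(drop(X %*% beta) + offv, 700))
  ll <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_outer)) {
    beta <- irls(beta, theta)
    mu <- mu_of(beta)
    opt <- optimize(function(lt) nb2_loglik(y, mu, exp(lt)),
                    interval = c(log(1e-4), log(1e8)),
                    maximum = TRUE, tol = 1e-10)
    theta <- exp(opt$maximum)
    new_ll <- opt$objective
    # at very large theta (Poisson limit) lgamma cancellation puts a noise
    # floor of order eps * n * theta under the log-likelihood; without this
    # allowance the 1e-8 criterion is unattainable on equidispersed data
    tol_eff <- tol + 1e-14 * length(y) * theta
    if (is.finite(ll) && abs(new_ll - ll) < tol_eff) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  if (!converged) {
    abort(sprintf(paste0("NB2 fit did not converge in %d iterations ",
                         "(last log-likelihood %.6f, theta %.4g)"),
                  max_outer, ll, theta),
          class = "nbrsf_convergence_error")
  }
  mu <- mu_of(beta)
  w <- mu / (1 + mu / theta)
  info <- crossprod(X * sqrt(w))
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  # curvature of the profile log-likelihood in log(theta)
  h <- 1e-4; lt <- log(theta)
  d2 <- (nb2_loglik(y, mu, exp(lt + h)) - 2 * ll + nb2_loglik(y, mu, exp(lt - h))) / h^2
  theta_se <- if (is.finite(d2) && d2 < 0) theta * sqrt(-1 / d2) else NA_real_

  list(beta = setNames(as.numeric(beta), colnames(X)), theta = theta,
       theta_se = theta_se, vcov = vcov, mu = mu, loglik = ll,
       iterations = iter)
}

#' Informal goodness-of-fit: residual deviance over degrees of freedom
#'
#' Returns `D / df`. Ratios substantially greater than 1 are evidence of
#' groupings in the data — typically the panel structure of per-animal GPS
#' fixes — or of other violations of the NB2 assumptions; there is no formal
#' test. When the ratio is inflated, ML standard errors understate the true
#' uncertainty and animal-level bootstrapping should be used.
#'
#' @param fit An [fit_nb2()] object.
#' @return The scalar deviance ratio.
#' @export
gof_deviance_ratio <- function(fit) {
  stopifnot(inherits(fit, "nb2_fit"))
  fit$deviance / fit$df
}

#' Average fitted probability of an empty sampling unit
#'
#' Computes `(1/n) * sum_i (theta / (theta + u_i))^theta` over the fitted
#' means, for comparison with the observed fraction of zero counts. A large
#' gap between the two suggests the zeros are not NB2-consistent (e.g. a
#' zero-inflated process); the comparison is diagnostic only — no
#' zero-inflated or hurdle model is fit here.
#'
#' @param fit An [fit_nb2()] object.
#' @param units Optional unit table with the model covariates (and counts);
#'   defaults to the modeling data stored in the fit.
#' @return The expected zero proportion (scalar in `[0, 1]`).
#' @export
expected_zero_proportion <- function(fit, units = NULL) {
  stopifnot(inherits(fit, "nb2_fit"))
  mu <- if (is.null(units)) {
    fit$fitted
  } else {
    X <- cbind(1, as.matrix(units[fit$covariates]))
    exp(pmin(drop(X %*% fit$beta) + fit$offset_log_total, 700))
  }
  mean((fit$theta / (fit$theta + mu))^fit$theta)
}

#' @export
print.nb2_fit <- function(x, ...) {
  cat("NB2 resource-selection fit\n")
  cat(sprintf("  units: %d   covariates: %d   offset log(T): %s\n",
              x$n, length(x$covariates),
              if (x$offset_log_total == 0) "none" else format(x$offset_log_total, digits = 6)))
  cat(sprintf("  theta: %.4g (SE %.3g)   deviance/df: %.3f   AIC: %.1f\n",
              x$theta, x$theta_se, gof_deviance_ratio(x), x$aic))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an NB2 fit into a coefficient table
#'
#' @param x An [fit_nb2()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error` (ML), `statistic`
#'   (Wald z) and `p.value`. ML standard errors are anti-conservative under
#'   panel data; see [bootstrap_by_animal()].
#' @method tidy nb2_fit
#' @export
tidy.nb2_fit <- function(x, ...) {
  z <- x$beta / x$se
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' One-row model summary of an NB2 fit
#'
#' @param x An [fit_nb2()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `df`, `theta`, `theta_se`, `deviance`,
#'   `deviance_ratio`, `logLik`, `AIC`, observed (`zero_observed`) and
#'   NB2-expected (`zero_expected`) zero-count proportions.
#' @method glance nb2_fit
#' @export
glance.nb2_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    df = x$df,
    theta = x$theta,
    theta_se = x$theta_se,
    deviance = x$deviance,
    deviance_ratio = gof_deviance_ratio(x),
    logLik = x$loglik,
    AIC = x$aic,
    zero_observed = mean(x$data$count == 0),
    zero_expected = expected_zero_proportion(x)
  )
}
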