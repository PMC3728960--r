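#' Among-animal inference by bootstrapping individual animals
#'
#' The animal — not the GPS fix — is the experimental unit: fixes within an
#' animal are spatially and temporally correlated, so resampling them would
#' understate the real uncertainty. Each bootstrap replicate draws `m` animals
#' with replacement from the `m` observed animals, pools their locations (an
#' animal drawn `k` times contributes its counts `k` times), recomputes the
#' per-unit counts and the replicate offset `log(T_b)` (`T_b` = total fixes in
#' the replicate), and refits the NB2 model. The point estimate is the fit to
#' the full pooled data; the SD of the replicate coefficients estimates each
#' SE, and the central `level` percentile interval of the replicates is the
#' confidence interval. The result is a marginal (population-averaged) model:
#' between- and within-animal variability are collapsed.
#'
#' Within-animal locations are never resampled; temporal correlation of fixes
#' is deliberately left untouched because the unit counts, not the fixes, are
#' the response. Replicates that fail to converge are dropped with a warning
#' and reported in `n_failed`; more than 20\% failures is an error.
#'
#' @param locations Tibble of GPS fixes: `animal_id`, `x`, `y` (meters);
#'   at least two distinct animals.
#' @param units Unit table with covariate columns (counts are recomputed
#'   internally per animal).
#' @param covariates Character vector of covariate column names.
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Nominal confidence level (default 0.90).
#' @param seed Integer seed; results are bit-reproducible.
#'
#' @return An object of class `nb_bootstrap`: `point_fit` (the pooled
#'   [fit_nb2()]), `replicates` (tibble, one row per successful replicate),
#'   `theta_reps`, `se`, `ci_lower`, `ci_upper` (type-7 percentile bounds),
#'   `level`, `B`, `n_failed`, `m`. Methods: [tidy()], [glance()], `print()`.
#' @examples
#' \donttest{
#' spec <- sim_spec(region(0, 0, 2000, 2000), n_animals = 5, fixes_per_animal = 100,
#'                  surfaces = list(g = function(x, y) x / 2000),
#'                  beta = c(g = 1), coef_sd = c(g = 0.2))
#' sim <- simulate_locations(spec, seed = 1)
#' u <- systematic_units(spec$region, 250, 100, seed = 2)
#' u <- add_surface_covariates(u, spec$surfaces)
#' bt <- bootstrap_by_animal(sim$locations, u, "g", B = 50, seed = 3)
#' tidy(bt)
#' }
#' @export
bootstrap_by_animal <- function(locations, units, covariates, B = 1000,
                                level = 0.90, seed = NULL) {
  stopifnot(B >= 2, level > 0, level < 1)
  ids <- sort(unique(locations$animal_id))
  m <- length(ids)
  if (m < 2L) {
    abort("bootstrap requires >= 2 experimental units (animals)",
          class = "nbrsf_bootstrap_error")
  }
  C <- animal_count_matrix(units, locations)      # n_units x m
  T_a <- as.numeric(table(factor(locations$animal_id, levels = ids)))

  pooled <- units
  pooled$count <- as.integer(rowSums(C))
  point_fit <- fit_nb2(pooled, covariates, offset_log_total = log(sum(T_a)))

  draw_indices <- if (is.null(seed)) {
    replicate(B, sample.int(m, m, replace = TRUE), simplify = FALSE)
  } else {
    withr::with_seed(as.integer(seed),
      replicate(B, sample.int(m, m, replace = TRUE), simplify = FALSE))
  }

  terms <- names(point_fit$beta)
  reps <- matrix(NA_real_, nrow = B, ncol = length(terms),
                 dimnames = list(NULL, terms))
  theta_reps <- rep(NA_real_, B)
  boot_units <- units
  for (b in seq_len(B)) {
    idx <- draw_indices[[b]]
    boot_units$count <- as.integer(rowSums(C[, idx, drop = FALSE]))
    fit_b <- tryCatch(
      fit_nb2(boot_units, covariates, offset_log_total = log(sum(T_a[idx]))),
      error = function(e) NULL
    )
    if (!is.null(fit_b)) {
      reps[b, ] <- fit_b$beta
      theta_reps[b] <- fit_b$theta
    }
  }
  ok <- !is.na(reps[, 1])
  n_failed <- sum(!ok)
  if (n_failed > 0) {
    warn(sprintf("%d of %d bootstrap replicates failed to converge and were dropped",
                 n_failed, B))
  }
  if (n_failed > 0.2 * B) {
    abort(sprintf("too many failed bootstrap replicates (%d of %d)", n_failed, B),
          class = "nbrsf_bootstrap_error")
  }
  reps_ok <- reps[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  # type-7 (linear interpolation) percentile convention, fixed
  ci <- apply(reps_ok, 2, quantile, probs = c(alpha, 1 - alpha), type = 7, names = FALSE)

  structure(
    list(
      point_fit = point_fit,
      replicates = tibble::as_tibble(as.data.frame(reps_ok, check.names = FALSE)),
      theta_reps = theta_reps[ok],
      se = apply(reps_ok, 2, sd),
      ci_lower = setNames(ci[1, ], terms),
      ci_upper = setNames(ci[2, ], terms),
      level = level,
      B = B,
      n_failed = n_failed,
      m = m,
      animals = ids,
      seed = seed
    ),
    class = "nb_bootstrap"
  )
}

#' @export
print.nb_bootstrap <- function(x, ...) {
  cat(sprintf("Animal-level bootstrap: %d animals, B = %d (%d failed), %g%% percentile CIs\n",
              x$m, x$B, x$n_failed, 100 * x$level))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Coefficient table of an animal-level bootstrap
#'
#' One row per model term: the pooled-data estimate, the ML standard error,
#' the bootstrap standard error (SD of replicates), and the percentile
#' confidence limits. Bootstrap SEs are typically larger than ML SEs when the
#' counts have panel (per-animal) structure.
#'
#' @param x An [bootstrap_by_animal()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `ml_se`, `boot_se`,
#'   `conf.low`, `conf.high`.
#' @method tidy nb_bootstrap
#' @export
tidy.nb_bootstrap <- function(x, ...) {
  tibble::tibble(
    term = names(x$point_fit$beta),
    estimate = unname(x$point_fit$beta),
    ml_se = unname(x$point_fit$se),
    boot_se = unname(x$se),
    conf.low = unname(x$ci_lower),
    conf.high = unname(x$ci_upper)
  )
}

#' @method glance nb_bootstrap
#' @export
glance.nb_bootstrap <- function(x, ...) {
  tibble::tibble(
    m = x$m, B = x$B, n_failed = x$n_failed, level = x$level,
    theta = x$point_fit$theta,
    theta_boot_se = sd(x$theta_reps)
  )
}

#' Two-stage estimation: fit per animal, average the coefficients
#'
#' Stage 1 fits a separate NB2 model (with offset `log(T_a)`, the animal's
#' own total fixes) to each animal's counts; stage 2 averages the coefficient
#' vectors with equal weight per animal and reports
#' `SE = SD(coefficients) / sqrt(m)`. Because each animal's intercept absorbs
#' its own scaling, the averaged model describes relative (geometric-mean)
#' selection — an RSF rather than an RSPF.
#'
#' Animals whose counts cannot support a fit (fewer than `p + 2` occupied
#' units, all zeros, or non-convergence) are excluded with a warning and
#' listed in `excluded`, never silently dropped.
#'
#' @inheritParams bootstrap_by_animal
#' @return An object of class `nb_two_stage`: `per_animal` (tibble of
#'   per-animal coefficients and theta), `mean_beta`, `se`, `m_used`,
#'   `excluded`. Methods: [tidy()], `print()`.
#' @export
two_stage <- function(locations, units, covariates) {
  ids <- sort(unique(locations$animal_id))
  C <- animal_count_matrix(units, locations)
  T_a <- as.numeric(table(factor(locations$animal_id, levels = ids)))
  p1 <- length(covariates) + 1L

  fits <- vector("list", length(ids))
  names(fits) <- ids
  for (a in seq_along(ids)) {
    au <- units
    au$count <- as.integer(C[, a])
    if (sum(au$count > 0) < p1 + 1L) next  # too few occupied units
    fits[[a]] <- tryCatch(
      fit_nb2(au, covariates, offset_log_total = log(T_a[a])),
      error = function(e) NULL
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  excluded <- ids[!ok]
  if (length(excluded)) {
    warn(paste0("two-stage fit excluded animal(s) with inestimable models: ",
                paste(excluded, collapse = ", ")))
  }
  m_used <- sum(ok)
  if (m_used < 2L) {
    abort("two-stage estimation needs >= 2 animals with estimable fits",
          class = "nbrsf_twostage_error")
  }
  coef_mat <- t(vapply(fits[ok], function(f) f$beta, numeric(p1)))
  per_animal <- tibble::as_tibble(as.data.frame(coef_mat, check.names = FALSE))
  per_animal <- dplyr::bind_cols(
    tibble::tibble(animal_id = ids[ok]),
    per_animal,
    tibble::tibble(theta = vapply(fits[ok], function(f) f$theta, numeric(1)))
  )
  structure(
    list(
      per_animal = per_animal,
      fits = fits[ok],
      mean_beta = colMeans(coef_mat),
      se = apply(coef_mat, 2, sd) / sqrt(m_used),
      m_used = m_used,
      excluded = excluded
    ),
    class = "nb_two_stage"
  )
}

#' @export
print.nb_two_stage <- function(x, ...) {
  cat(sprintf("Two-stage NB2 estimate over %d animals%s\n", x$m_used,
              if (length(x$excluded))
                paste0(" (excluded: ", paste(x$excluded, collapse = ", "), ")")
              else ""))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @method tidy nb_two_stage
#' @export
tidy.nb_two_stage <- function(x, ...) {
  tibble::tibble(
    term = names(x$mean_beta),
    estimate = unname(x$mean_beta),
    std.error = unname(x$se)
  )
}

#' Percent change in expected relative use per covariate change
#'
#' Under the log link, a coefficient `b` implies a multiplicative change
#' `exp(b * delta)` in expected relative use per `delta` change in the
#' covariate, other covariates held fixed. This returns it as a percentage,
#' `100 * (exp(b * delta) - 1)`. Field usage often calls `exp(b)` an "odds
#' ratio"; under a log link it is strictly a rate (risk) ratio, and that is
#' the quantity computed here.
#'
#' @param coef Coefficient on the covariate (log-link scale).
#' @param delta Change in the covariate, in its own units (default 1).
#' @return Percent change in expected relative use.
#' @examples
#' rate_ratio(-0.355, 1)  # ~ -30% per unit increase
#' rate_ratio(0.022, 1)   # ~ +2.2% per unit increase
#' @export
rate_ratio <- function(coef, delta = 1) {
  stopifnot(is.finite(coef), is.finite(delta))
  100 * (exp(coef * delta) - 1)
}
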