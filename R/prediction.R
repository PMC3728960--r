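#' Predicted relative frequency of use for sampling units
#'
#' Computes `exp(beta_0 + sum_j beta_j x_ji)` for each unit — the relative
#' frequency (probability-of-use) scale. The training offset `log(T)` is NOT
#' added: it scaled the response during fitting, so leaving it out is what
#' makes predictions relative frequencies rather than counts. Set
#' `scale = "count"` to multiply by `T` and recover expected counts.
#'
#' Predictions for units with covariates outside the ranges seen during
#' modeling are extrapolations; they trigger a warning (not an error, since
#' mapping grids routinely extend slightly past the sampled units).
#' Prediction units must share the modeling radius: the response was defined
#' on discs of that size.
#'
#' @param fit An [fit_nb2()] object.
#' @param new_units Unit table (or any tibble) with the model covariates;
#'   may overlap or form a fine grid.
#' @param rescale `"none"` (default), `"max1"` (divide by the maximum, so the
#'   best unit scores 1), or `"unit_sum"` (divide by the sum, a probability
#'   vector over the supplied units).
#' @param scale `"relative"` (default) or `"count"` (multiply by
#'   `exp(offset_log_total)`; only meaningful with `rescale = "none"`).
#'
#' @return `new_units` with a `.pred` column, classed `nb_prediction` so
#'   [autoplot()] draws a surface when centers are present.
#' @export
predict_units <- function(fit, new_units,
                          rescale = c("none", "max1", "unit_sum"),
                          scale = c("relative", "count")) {
  stopifnot(inherits(fit, "nb2_fit"))
  rescale <- match.arg(rescale)
  scale <- match.arg(scale)
  missing_cov <- setdiff(fit$covariates, names(new_units))
  if (length(missing_cov)) {
    abort(paste0("unknown covariate column(s): ", paste(missing_cov, collapse = ", ")),
          class = "nbrsf_predict_error")
  }
  if ("radius" %in% names(new_units) && is.finite(fit$radius) &&
      any(new_units$radius != fit$radius)) {
    abort(sprintf("unit radius mismatch: model used %g m", fit$radius),
          class = "nbrsf_predict_error")
  }
  check_covariate_ranges(fit, new_units)
  X <- cbind(1, as.matrix(new_units[fit$covariates]))
  pred <- exp(drop(X %*% fit$beta))
  if (scale == "count") pred <- pred * exp(fit$offset_log_total)
  pred <- switch(rescale,
    none = pred,
    max1 = pred / max(pred),
    unit_sum = pred / sum(pred)
  )
  out <- tibble::as_tibble(new_units)
  out$.pred <- pred
  class(out) <- c("nb_prediction", class(out))
  attr(out, "rescale") <- rescale
  out
}

check_covariate_ranges <- function(fit, new_units) {
  for (cv in fit$covariates) {
    rng <- range(fit$data[[cv]])
    v <- new_units[[cv]]
    n_out <- sum(v < rng[1] | v > rng[2])
    if (n_out > 0) {
      warn(sprintf(
        "covariate '%s': %d prediction value(s) outside the modeled range [%g, %g]; predictions there are extrapolations",
        cv, n_out, rng[1], rng[2]))
    }
  }
  invisible(TRUE)
}

#' Predictive surface on a fine lattice of (possibly overlapping) units
#'
#' Evaluates the fitted relative-frequency model on a fine grid of circular
#' units of the modeling radius. Mapping at a finer scale than the modeling
#' sample is valid, and the grid units may overlap; consequently the raw
#' predictions need not sum to 1 — use `rescale = "unit_sum"` if a
#' probability-of-use map is wanted, or `"max1"` for a 0–1 habitat-quality
#' map.
#'
#' @inheritParams predict_units
#' @param grid Tibble with `center_x`, `center_y` and the model covariates
#'   (e.g. built with [add_surface_covariates()] on a lattice of centers).
#' @return A classed tibble of predictions; see [predict_units()].
#' @export
prediction_surface <- function(fit, grid, rescale = c("none", "max1", "unit_sum")) {
  if (!all(c("center_x", "center_y") %in% names(grid))) {
    abort("grid needs center_x and center_y columns", class = "nbrsf_predict_error")
  }
  if (!"radius" %in% names(grid)) grid$radius <- fit$radius
  predict_units(fit, grid, rescale = match.arg(rescale))
}

#' Marginal covariate profile with bootstrap envelope
#'
#' Sweeps one covariate across its observed range (never beyond: predictions
#' should stay within the modeling data) while holding all other covariates
#' at reference values (observed medians by default). Every bootstrap
#' replicate's coefficient vector is evaluated on the grid; the per-point
#' median is the profile and the central `level` percentiles form the
#' envelope. All three curves are jointly divided by their overall maximum,
#' so the global maximum of the display is exactly 1.
#'
#' @param boot An [bootstrap_by_animal()] object.
#' @param covariate Name of the covariate to profile.
#' @param n_grid Number of grid points across the observed range.
#' @param reference Optional named list/vector of values for the held-fixed
#'   covariates; defaults to their observed medians over the modeling units.
#' @param level Envelope level (default the bootstrap's own `level`).
#'
#' @return A tibble of class `nb_marginal_profile` with columns `value`
#'   (covariate grid), `median`, `lower`, `upper` (scaled so max = 1).
#'   [autoplot()] draws the profile with its envelope.
#' @export
marginal_profile <- function(boot, covariate, n_grid = 50, reference = NULL,
                             level = NULL) {
  stopifnot(inherits(boot, "nb_bootstrap"))
  fit <- boot$point_fit
  if (!covariate %in% fit$covariates) {
    abort(sprintf("covariate '%s' is not in the fitted model", covariate),
          class = "nbrsf_predict_error")
  }
  level <- level %||% boot$level
  data <- fit$data
  grid <- seq(min(data[[covariate]]), max(data[[covariate]]), length.out = n_grid)

  ref <- vapply(fit$covariates, function(cv) median(data[[cv]]), numeric(1))
  if (!is.null(reference)) {
    bad <- setdiff(names(reference), fit$covariates)
    if (length(bad)) {
      abort(paste0("reference values for unknown covariate(s): ",
                   paste(bad, collapse = ", ")), class = "nbrsf_predict_error")
    }
    ref[names(reference)] <- unlist(reference)
  }
  X <- matrix(rep(c(1, ref), each = n_grid), nrow = n_grid,
              dimnames = list(NULL, c("(Intercept)", fit$covariates)))
  X[, covariate] <- grid

  reps <- as.matrix(boot$replicates)           # B x (p+1)
  preds <- exp(X %*% t(reps))                  # n_grid x B
  alpha <- (1 - level) / 2
  med <- apply(preds, 1, median)
  lo <- apply(preds, 1, quantile, probs = alpha, type = 7, names = FALSE)
  hi <- apply(preds, 1, quantile, probs = 1 - alpha, type = 7, names = FALSE)
  sc <- max(med, lo, hi)

  out <- tibble::tibble(value = grid, median = med / sc,
                        lower = lo / sc, upper = hi / sc)
  class(out) <- c("nb_marginal_profile", class(out))
  attr(out, "covariate") <- covariate
  attr(out, "reference") <- ref[setdiff(fit$covariates, covariate)]
  attr(out, "level") <- level
  out
}

#' Plot a marginal covariate profile
#'
#' @param object An [marginal_profile()] result.
#' @param ... Unused.
#' @return A ggplot: median predicted relative use (scaled to max 1) with the
#'   bootstrap percentile envelope.
#' @method autoplot nb_marginal_profile
#' @export
autoplot.nb_marginal_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(
      x = attr(object, "covariate"),
      y = "predicted relative use (max = 1)",
      title = sprintf("Marginal profile of %s (%g%% bootstrap envelope)",
                      attr(object, "covariate"), 100 * attr(object, "level"))
    )
}

#' Plot a prediction surface
#'
#' @param object A [predict_units()] / [prediction_surface()] result with
#'   `center_x` / `center_y` columns.
#' @param ... Unused.
#' @return A ggplot tile map of predicted relative use.
#' @method autoplot nb_prediction
#' @export
autoplot.nb_prediction <- function(object, ...) {
  if (!all(c("center_x", "center_y") %in% names(object))) {
    abort("prediction table has no center coordinates to map",
          class = "nbrsf_predict_error")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center_x, y = .data$center_y,
                                       fill = .data$.pred)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "relative use")
}

#' Plot a sampling-unit design
#'
#' Draws unit outlines (circles) over the region, shaded by count when
#' counts are present.
#'
#' @param units A unit table.
#' @param n_vertices Circle resolution.
#' @return A ggplot of the design.
#' @export
plot_units <- function(units, n_vertices = 60) {
  check_unit_table(units)
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)
  circles <- tidyr::crossing(i = seq_len(nrow(units)), ang = ang) |>
    dplyr::mutate(
      x = units$center_x[.data$i] + units$radius[.data$i] * cos(.data$ang),
      y = units$center_y[.data$i] + units$radius[.data$i] * sin(.data$ang),
      count = if ("count" %in% names(units)) units$count[.data$i] else NA_real_
    )
  p <- ggplot2::ggplot(circles, ggplot2::aes(x = .data$x, y = .data$y,
                                             group = .data$i))
  p <- if ("count" %in% names(units)) {
    p + ggplot2::geom_polygon(ggplot2::aes(fill = .data$count), colour = "grey30",
                              linewidth = 0.2)
  } else {
    p + ggplot2::geom_polygon(fill = NA, colour = "grey30", linewidth = 0.2)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("%s design, %d units", design_kind(units), nrow(units)))
}
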