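#' Read a GPS-locations CSV
#'
#' Expects a header `animal_id,time,x,y`: one row per fix, `time` an ISO-8601
#' timestamp, `x`/`y` planar meters. Timestamps are validated for
#' parseability only — the estimator never uses them. Malformed rows
#' (unparseable numbers or timestamps, or a duplicated header line mid-file)
#' are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble `animal_id` (character), `time` (POSIXct, UTC), `x`, `y`.
#' @export
read_locations <- function(path) {
  check_file_exists(path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort("empty locations file", class = "nbrsf_io_error")
  missing <- setdiff(c("animal_id", "time", "x", "y"), names(raw))
  if (length(missing)) {
    abort(paste0("missing column: ", paste(missing, collapse = ", ")),
          class = "nbrsf_io_error")
  }
  dup <- which(raw$animal_id == "animal_id" & raw$time == "time")
  if (length(dup)) {
    abort(paste0("duplicated header row at line ", dup[1] + 1L),
          class = "nbrsf_io_error")
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  tm <- suppressWarnings(readr::parse_datetime(raw$time))
  bad <- which(!is.finite(x) | !is.finite(y) | is.na(tm))
  if (length(bad)) {
    abort(paste0("malformed row(s) at line(s): ",
                 paste(head(bad + 1L, 10), collapse = ", ")),
          class = "nbrsf_io_error")
  }
  tibble::tibble(animal_id = raw$animal_id, time = tm, x = x, y = y)
}

#' Read / write a sampling-unit CSV
#'
#' Columns: `unit_id`, `center_x`, `center_y`, `radius`, then covariate
#' columns, then (optionally) `count`. Writing then reading reproduces the
#' table (doubles at full precision). Non-numeric or missing covariate values
#' are an error naming the offending column.
#'
#' @param path Path to the CSV file.
#' @return `read_units()`: a tibble with `design_kind` attribute
#'   `"user_supplied"` (unless the file was written by [write_units()], which
#'   stores the design kind in a comment line).
#' @export
read_units <- function(path) {
  check_file_exists(path)
  first <- readLines(path, n = 1L)
  design <- if (startsWith(first, "# design_kind:")) {
    trimws(sub("# design_kind:", "", first))
  } else "user_supplied"
  units <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    unit_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  check_unit_table(units)
  covs <- setdiff(names(units), c("unit_id", "center_x", "center_y", "radius", "count"))
  for (cv in covs) {
    if (!is.numeric(units[[cv]]) || any(!is.finite(units[[cv]]))) {
      abort(paste0("covariate column contains non-numeric or missing values: ", cv),
            class = "nbrsf_io_error")
    }
  }
  if ("count" %in% names(units)) units$count <- as.integer(units$count)
  attr(units, "design_kind") <- design
  units
}

#' @param units A unit table.
#' @rdname read_units
#' @export
write_units <- function(units, path) {
  check_unit_table(units)
  writeLines(paste0("# design_kind: ", design_kind(units)), path)
  readr::write_csv(units, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Serialize a fit or bootstrap result to JSON
#'
#' Writes every estimation field plus a provenance block (package and R
#' versions, the echoed configuration). Identical inputs give byte-identical
#' files. [read_fit()] rebuilds an `nb2_fit` sufficient for prediction from a
#' fit report.
#'
#' @param x An `nb2_fit` or `nb_bootstrap` object.
#' @param path Output path.
#' @export
write_fit <- function(x, path) {
  prov <- list(
    package = "nbrsf",
    package_version = as.character(utils::packageVersion("nbrsf")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  if (inherits(x, "nb2_fit")) {
    payload <- list(
      type = "nb2_fit",
      beta = as.list(x$beta),
      theta = x$theta,
      theta_se = x$theta_se,
      ml_se = as.list(x$se),
      vcov = x$vcov,
      deviance = x$deviance,
      df = x$df,
      n = x$n,
      loglik = x$loglik,
      aic = x$aic,
      deviance_ratio = gof_deviance_ratio(x),
      zero_observed = mean(x$data$count == 0),
      zero_expected = expected_zero_proportion(x),
      offset_log_total = x$offset_log_total,
      covariates = x$covariates,
      radius = x$radius,
      covariate_ranges = lapply(setNames(x$covariates, x$covariates),
                                function(cv) range(x$data[[cv]])),
      provenance = prov
    )
  } else if (inherits(x, "nb_bootstrap")) {
    payload <- list(
      type = "nb_bootstrap",
      table = tidy(x),
      theta = x$point_fit$theta,
      level = x$level, B = x$B, n_failed = x$n_failed, m = x$m,
      seed = x$seed,
      replicates = as.matrix(x$replicates),
      theta_reps = x$theta_reps,
      provenance = prov
    )
  } else {
    abort("write_fit() handles nb2_fit and nb_bootstrap objects",
          class = "nbrsf_io_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @return `read_fit()`: an `nb2_fit` usable with [predict_units()] (the
#'   modeling rows themselves are not stored; covariate ranges are, so
#'   extrapolation warnings still work).
#' @export
read_fit <- function(path) {
  check_file_exists(path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "nb2_fit")) {
    abort("not an nb2_fit report", class = "nbrsf_io_error")
  }
  beta <- unlist(j$beta)
  rng <- j$covariate_ranges
  fake_data <- tibble::as_tibble(lapply(rng, function(r) as.numeric(r)))
  fake_data$count <- NA_integer_
  structure(
    list(beta = beta, theta = j$theta, theta_se = j$theta_se,
         se = unlist(j$ml_se), vcov = j$vcov,
         deviance = j$deviance, df = j$df, n = j$n, loglik = j$loglik,
         aic = j$aic, offset_log_total = j$offset_log_total,
         covariates = j$covariates, fitted = NULL,
         radius = j$radius %||% NA_real_,
         data = fake_data, iterations = NA_integer_),
    class = "nb2_fit"
  )
}

check_file_exists <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nbrsf_io_error")
  }
  invisible(path)
}
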