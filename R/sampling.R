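#' Simple random sample (with replacement) of circular sampling units
#'
#' Draws `n` unit centers uniformly and independently over the region.
#' Because the draw is with replacement over continuous space, units may
#' overlap; a location falling inside several units is counted in each of
#' them, which keeps the unit counts free of a sum-to-T constraint.
#' Unit discs may extend beyond the region boundary: only centers are
#' required to fall inside, mirroring designs whose covariates are measured
#' on footprints that can cross the study-area edge.
#'
#' @param region An [region()] object (or `c(xmin, ymin, xmax, ymax)`).
#' @param n Number of units to draw (>= 1).
#' @param radius Unit radius, meters. All units share one radius.
#' @param seed Integer seed; the design is reproducible bit-for-bit.
#'
#' @return A tibble with columns `unit_id`, `center_x`, `center_y`, `radius`,
#'   carrying attribute `design_kind = "random_replacement"`.
#' @examples
#' u <- random_units(region(0, 0, 1000, 1000), n = 100, radius = 50, seed = 1)
#' nrow(u)
#' @export
random_units <- function(region, n, radius, seed) {
  region <- as_region(region)
  stopifnot(n >= 1, radius > 0)
  if (2 * radius > min(region_width(region), region_height(region))) {
    abort("region too small for units of this radius", class = "nbrsf_design_error")
  }
  n <- as.integer(n)
  centers <- withr::with_seed(as.integer(seed), {
    # rejection sampling against the polygon keeps centers uniform on it
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      need <- n - length(xs)
      cx <- runif(2L * need + 10L, region$xmin, region$xmax)
      cy <- runif(2L * need + 10L, region$ymin, region$ymax)
      keep <- region_contains(region, cx, cy)
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    cbind(xs[seq_len(n)], ys[seq_len(n)])
  })
  new_unit_table(centers[, 1], centers[, 2], radius, "random_replacement")
}

#' Systematic sample of nonoverlapping circular units with a random start
#'
#' Lays a square lattice of centers with spacing `spacing` and a seeded
#' uniform random origin offset in `[0, spacing)^2`; centers falling outside
#' the region are dropped. `spacing >= 2 * radius` guarantees the discs do
#' not overlap, so each location is counted in at most one unit.
#'
#' @inheritParams random_units
#' @param spacing Lattice spacing, meters; must be at least `2 * radius`.
#'
#' @return A tibble of units (see [random_units()]) with
#'   `design_kind = "systematic_random_start"`.
#' @examples
#' u <- systematic_units(region(0, 0, 1000, 1000), spacing = 400, radius = 200, seed = 7)
#' @export
systematic_units <- function(region, spacing, radius, seed) {
  region <- as_region(region)
  stopifnot(radius > 0, spacing > 0)
  if (spacing < 2 * radius) {
    abort("units would overlap: spacing must be at least twice the radius",
          class = "nbrsf_design_error")
  }
  if (spacing > max(region_width(region), region_height(region))) {
    abort("spacing exceeds the region extent", class = "nbrsf_design_error")
  }
  off <- withr::with_seed(as.integer(seed), runif(2, 0, spacing))
  gx <- seq(region$xmin + off[1], region$xmax, by = spacing)
  gy <- seq(region$ymin + off[2], region$ymax, by = spacing)
  centers <- expand.grid(x = gx, y = gy)
  keep <- region_contains(region, centers$x, centers$y)
  centers <- centers[keep, , drop = FALSE]
  if (nrow(centers) == 0L) {
    abort("no lattice centers fall inside the region", class = "nbrsf_design_error")
  }
  new_unit_table(centers$x, centers$y, radius, "systematic_random_start")
}

new_unit_table <- function(cx, cy, radius, design_kind) {
  out <- tibble::tibble(
    unit_id = sprintf("u%04d", seq_along(cx)),
    center_x = as.numeric(cx),
    center_y = as.numeric(cy),
    radius = as.numeric(radius)
  )
  attr(out, "design_kind") <- design_kind
  out
}

#' Design kind of a unit table
#'
#' @param units A unit table created by [random_units()], [systematic_units()]
#'   or [read_units()].
#' @return `"random_replacement"`, `"systematic_random_start"` or
#'   `"user_supplied"`.
#' @export
design_kind <- function(units) {
  attr(units, "design_kind") %||% "user_supplied"
}

check_unit_table <- function(units) {
  need <- c("unit_id", "center_x", "center_y", "radius")
  missing <- setdiff(need, names(units))
  if (length(missing)) {
    abort(paste0("unit table missing column(s): ", paste(missing, collapse = ", ")),
          class = "nbrsf_units_error")
  }
  if (any(units$radius <= 0)) abort("unit radius must be positive", class = "nbrsf_units_error")
  if (length(unique(units$radius)) > 1L) {
    abort("all sampling units must share one radius", class = "nbrsf_units_error")
  }
  invisible(units)
}

#' Count animal locations inside each sampling unit
#'
#' A location is counted in a unit when its Euclidean distance to the unit
#' center is `<= radius` (closed disc: a point exactly on the boundary is
#' inside). With overlapping units a location contributes to every unit that
#' contains it, so the unit counts are not constrained to sum to the number
#' of locations — the property that lets the counts be modeled as independent
#' negative binomial draws rather than a multinomial vector.
#'
#' @param units A unit table ([random_units()], [systematic_units()],
#'   [read_units()], or any tibble with `center_x`, `center_y`, `radius`).
#' @param locations A tibble with columns `animal_id`, `x`, `y` (meters, same
#'   planar coordinate system as the units). Zero rows are valid and give all
#'   counts zero.
#' @param animals Optional character vector: count only these animals' fixes.
#'
#' @return `units` with a `count` column (non-negative integer) added or
#'   replaced.
#' @examples
#' u <- tibble::tibble(unit_id = "u1", center_x = 0, center_y = 0, radius = 1)
#' locs <- tibble::tibble(animal_id = "a", x = c(0, 0.5, 2), y = 0)
#' count_locations(u, locs)$count # 2
#' @export
count_locations <- function(units, locations, animals = NULL) {
  check_unit_table(units)
  if (!all(c("x", "y") %in% names(locations))) {
    abort("locations need columns x and y", class = "nbrsf_locations_error")
  }
  if (!is.null(animals)) {
    locations <- locations[locations$animal_id %in% animals, , drop = FALSE]
  }
  units$count <- count_in_discs(units$center_x, units$center_y, units$radius,
                                locations$x, locations$y)
  units
}

# per-unit closed-disc point counts; loops over units, vectorized over points
count_in_discs <- function(cx, cy, r, px, py) {
  if (length(px) == 0L) return(integer(length(cx)))
  if (any(!is.finite(px)) || any(!is.finite(py))) {
    abort("locations contain non-finite coordinates", class = "nbrsf_locations_error")
  }
  r2 <- r^2
  vapply(seq_along(cx), function(i) {
    sum((px - cx[i])^2 + (py - cy[i])^2 <= r2[i])
  }, integer(1))
}

# n_units x n_animals matrix of per-animal counts (bootstrap workhorse:
# pooled counts for any animal multiset are row sums over its columns)
animal_count_matrix <- function(units, locations) {
  check_unit_table(units)
  ids <- sort(unique(locations$animal_id))
  m <- vapply(ids, function(a) {
    sel <- locations$animal_id == a
    count_in_discs(units$center_x, units$center_y, units$radius,
                   locations$x[sel], locations$y[sel])
  }, integer(nrow(units)))
  m <- matrix(m, nrow = nrow(units), dimnames = list(units$unit_id, ids))
  m
}

#' Evaluate covariate surfaces at unit centers
#'
#' Adds one column per named surface function, evaluated at each unit center.
#' Surfaces are deterministic functions `f(x, y)` of planar coordinates
#' (meters), as used by the synthetic-data generator ([sim_spec()]).
#'
#' @inheritParams count_locations
#' @param surfaces Named list of functions `f(x, y)`.
#' @return `units` with one numeric column per surface.
#' @export
add_surface_covariates <- function(units, surfaces) {
  check_unit_table(units)
  stopifnot(is.list(surfaces), !is.null(names(surfaces)), all(nzchar(names(surfaces))))
  for (nm in names(surfaces)) {
    units[[nm]] <- as.numeric(surfaces[[nm]](units$center_x, units$center_y))
  }
  units
}
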