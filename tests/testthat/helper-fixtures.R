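# Fixtures are built in code; nothing is read from disk except io tests'
# own temporary files.

# bare unit table with one uniform covariate x (no geometry involved)
mk_units_1d <- function(n, seed = 100) {
  withr::with_seed(seed, tibble::tibble(
    unit_id = sprintf("u%04d", seq_len(n)),
    center_x = 0, center_y = 0, radius = 100,
    x = runif(n)
  ))
}

# smooth well-specified simulation world shared by loop-recovery and
# marginal-profile tests: surfaces vary slowly relative to the unit radius
# and the unit design covers ~40% of the region, so unit counts behave as
# Poisson sampling of the underlying intensity
smooth_world <- function() {
  spec <- sim_spec(
    region(0, 0, 4000, 4000), n_animals = 8, fixes_per_animal = 250,
    surfaces = list(
      grad = function(x, y) x / 4000,
      soils = function(x, y) sin(2 * pi * x / 3000) * sin(2 * pi * y / 3000),
      rad = function(x, y) sqrt((x - 2000)^2 + (y - 2000)^2) / 1000
    ),
    beta = c(grad = 1, soils = 0.5, rad = -0.3),
    coef_sd = c(grad = 0.1, soils = 0.05, rad = 0.05)
  )
  units <- systematic_units(region(150, 150, 3850, 3850), 400, 150, seed = 11)
  units <- add_surface_covariates(units, spec$surfaces)
  list(spec = spec, units = units)
}

# panel world with strong among-animal heterogeneity on the gradient slope
# plus fine-scale patchiness the model does not fit
panel_spec <- function(heterogeneous = TRUE) {
  sim_spec(
    region(0, 0, 3000, 3000), n_animals = 8, fixes_per_animal = 200,
    surfaces = list(
      g = function(x, y) x / 3000,
      patch = function(x, y) sin(2 * pi * x / 700) * sin(2 * pi * y / 800)
    ),
    beta = c(g = 1, patch = 0.8),
    coef_sd = if (heterogeneous) c(g = 0.8, patch = 0.3) else NULL
  )
}

panel_units <- function() {
  u <- systematic_units(region(0, 0, 3000, 3000), 250, 100, seed = 1)
  add_surface_covariates(u, list(g = function(x, y) x / 3000))
}

# three animals with bit-identical fix locations (degenerate resampling)
identical_animal_locations <- function(n_fixes = 80, seed = 5) {
  base <- withr::with_seed(seed, tibble::tibble(
    x = runif(n_fixes, 0, 3000), y = runif(n_fixes, 0, 3000)
  ))
  dplyr::bind_rows(lapply(c("a1", "a2", "a3"), function(id) {
    tibble::tibble(animal_id = id,
                   time = as.POSIXct("2010-08-01", tz = "UTC") + 3600 * seq_len(n_fixes),
                   x = base$x, y = base$y)
  }))
}
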