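# Fixtures built in code: tiny grids and hand-controllable meteorology.

tiny_grid <- function(nr = 5, nc = 5, cell = 12) domain_grid(nr, nc, cell)

# A fire_met object filled with constants (overridable per variable), for
# hand-written scheduling and dispersion fixtures.
constant_met <- function(grid, wind = 0, wind_dir = 0, temp = 20, rh = 0.35,
                         soil = 0.2) {
  mk <- function(v) array(v, dim = c(365, grid$n_rows, grid$n_cols))
  structure(list(grid = grid, wind = mk(wind), wind_dir = mk(wind_dir),
                 temp = mk(temp), rh = mk(rh), soil = mk(soil)),
            class = "fire_met")
}

# Random meteorology spanning the burn-window bounds, so roughly 20% of
# days pass the strict window: exercises filters, fallback and ties.
random_met <- function(grid, seed) {
  set.seed(seed)
  n <- 365 * grid$n_rows * grid$n_cols
  mk <- function(lo, hi) array(runif(n, lo, hi),
                               dim = c(365, grid$n_rows, grid$n_cols))
  structure(list(grid = grid, wind = mk(0, 8), wind_dir = mk(0, 360),
                 temp = mk(15, 35), rh = mk(0.20, 0.50),
                 soil = mk(0.10, 0.35)),
            class = "fire_met")
}

# independent strict-window filter (reimplemented from first principles)
brute_force_strict <- function(met, r, c, days, cr = burn_window_criteria()) {
  ok <- logical(length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    ok[i] <- met$wind[d, r, c] < cr$max_wind &&
      met$temp[d, r, c] < cr$max_temp &&
      met$rh[d, r, c] >= cr$rh_range[1] &&
      met$rh[d, r, c] <= cr$rh_range[2] &&
      met$soil[d, r, c] >= cr$soil_moisture_range[1] &&
      met$soil[d, r, c] <= cr$soil_moisture_range[2]
  }
  ok
}

random_beds <- function(n, seed, max_loading = 1e6) {
  set.seed(seed)
  data.frame(canopy = runif(n, 0, max_loading),
             shrub = runif(n, 0, max_loading),
             nonwoody = runif(n, 0, max_loading),
             woody = runif(n, 0, max_loading),
             duff = runif(n, 0, max_loading))
}

# emissions array with a single point source
point_emission <- function(grid, day, row, col, mass_g) {
  arr <- array(0, dim = c(365, grid$n_rows, grid$n_cols))
  arr[day, row, col] <- mass_g
  arr
}
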