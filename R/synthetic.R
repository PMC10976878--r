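#' Configuration for the synthetic input generators
#'
#' Bundles every tunable of the seeded generators. Defaults emulate the
#' structure of a Northern-California fire year: fire ignitions concentrated
#' May-September with heavy-tailed (lognormal) sizes; spring/fall meteorology
#' in which a large share of days satisfies the prescribed-burn window while
#' summer days almost never do; wind that tends toward the populated south of
#' the domain in spring/fall and toward the northeast in summer; population
#' clustered in the southern part of the domain; and fuel beds mixing
#' canopy/shrub/nonwoody/woody/duff loadings so forest, shrubland and
#' grassland cover types all occur.
#'
#' @param seed Integer RNG seed. Identical seeds give bit-identical outputs
#'   from every generator.
#' @param year Calendar-year label (non-leap 365-day calendar is always used).
#' @param n_fires Number of fire events to generate.
#' @param fire_size List with `meanlog`, `sdlog` of the lognormal burned-area
#'   distribution in km2. The default mean size is 1.4 km2 (140 ha) with a
#'   heavy tail.
#' @param season_weights Length-12 non-negative monthly ignition weights,
#'   normalized internally to probabilities.
#' @param met_params Named list with elements `winter`, `spring`, `summer`,
#'   `fall`; each a list of length-2 `c(mean, sd)` vectors for `wind` (m/s),
#'   `temp` (deg C), `rh` (fraction), `soil` (m3/m3) and `dir` (degrees,
#'   bearing the wind blows toward, clockwise from north).
#' @param population List with `n_clusters`, `total`, `dispersion_km`
#'   (cluster spread), and `south_frac` (clusters are centred within this
#'   southern fraction of the domain rows).
#' @param fuel List with cover-type probabilities `p_forest`, `p_shrub`,
#'   `p_grass`, per-type mean loadings (kg/km2) and a lognormal `sdlog`
#'   loading spread.
#' @param multi_day List controlling multi-day fire events: fires larger than
#'   `threshold_km2` are split over up to `max_days` consecutive days, and
#'   with probability `p_spread` later days spill into an adjacent cell.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         year = 2012L,
                         n_fires = 200L,
                         fire_size = list(meanlog = log(1.4) - 1.8^2 / 2,
                                          sdlog = 1.8),
                         season_weights = c(1, 1, 2, 3, 10, 20,
                                            25, 20, 10, 4, 2, 2),
                         met_params = default_met_params(),
                         population = list(n_clusters = 3L, total = 2e6,
                                           dispersion_km = 30,
                                           south_frac = 0.35),
                         fuel = list(p_forest = 0.5, p_shrub = 0.3,
                                     p_grass = 0.2,
                                     forest = c(canopy = 1e6, shrub = 0.5e5,
                                                nonwoody = 0.3e5, woody = 6e5,
                                                duff = 5e5),
                                     shrubland = c(canopy = 0.3e5, shrub = 8e5,
                                                   nonwoody = 1e5, woody = 1e5,
                                                   duff = 1e5),
                                     grassland = c(canopy = 0, shrub = 0.5e5,
                                                   nonwoody = 3e5,
                                                   woody = 0.3e5,
                                                   duff = 0.5e5),
                                     sdlog = 0.3),
                         multi_day = list(threshold_km2 = 10, max_days = 4L,
                                          p_spread = 0.3)) {
  stopifnot(length(season_weights) == 12, all(season_weights >= 0),
            sum(season_weights) > 0,
            fire_size$sdlog >= 0, n_fires >= 0,
            population$n_clusters >= 1, population$total >= 0,
            population$dispersion_km >= 0)
  for (s in c("winter", "spring", "summer", "fall")) {
    p <- met_params[[s]]
    if (is.null(p)) stop("met_params must contain season '", s, "'")
    for (v in c("wind", "temp", "rh", "soil", "dir")) {
      if (length(p[[v]]) != 2 || !is.numeric(p[[v]]))
        stop("met_params$", s, "$", v, " must be numeric c(mean, sd)")
      if (p[[v]][2] < 0)
        stop("met_params$", s, "$", v, " has negative sd")
    }
  }
  structure(
    list(seed = as.integer(seed), year = as.integer(year),
         n_fires = as.integer(n_fires), fire_size = fire_size,
         season_weights = season_weights / sum(season_weights),
         met_params = met_params, population = population, fuel = fuel,
         multi_day = multi_day),
    class = "synth_config"
  )
}

#' Default seasonal meteorology parameters
#'
#' Spring and fall are calm, cool and moist enough that many days fall inside
#' the prescribed-burn window; summer is hot and dry so essentially none do.
#' Wind bearings (degrees clockwise from north, blowing-toward) default to
#' southward transport in spring/fall and northeastward in summer, producing
#' the transport contrast between fire seasons.
#' @return Named list of per-season parameter lists (see [synth_config()]).
#' @export
default_met_params <- function() {
  list(
    winter = list(wind = c(4, 2), temp = c(8, 5), rh = c(0.60, 0.12),
                  soil = c(0.35, 0.08), dir = c(90, 40)),
    spring = list(wind = c(3, 1.5), temp = c(18, 6), rh = c(0.35, 0.08),
                  soil = c(0.22, 0.05), dir = c(180, 50)),
    summer = list(wind = c(4, 2), temp = c(30, 5), rh = c(0.15, 0.07),
                  soil = c(0.08, 0.04), dir = c(45, 40)),
    fall = list(wind = c(3, 1.5), temp = c(20, 6), rh = c(0.35, 0.08),
                soil = c(0.22, 0.05), dir = c(170, 50))
  )
}

# 3x3 box smoothing with edge renormalization; preserves mean, adds spatial
# coherence to the cell-level noise fields.
smooth_field <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == 1 && nc == 1) return(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  cnt <- matrix(0, nr + 2, nc + 2)
  cnt[2:(nr + 1), 2:(nc + 1)] <- 1
  acc <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    acc <- acc + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    den <- den + cnt[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  acc / den
}

#' Generate a year of daily gridded meteorology
#'
#' For each day, each variable is the seasonal mean plus a domain-wide daily
#' anomaly and a spatially smoothed cell-level anomaly (equal variance
#' shares), truncated to physical ranges: wind >= 0, relative humidity and
#' soil moisture in \[0, 1\]. Wind direction is a bearing in degrees
#' (blowing-toward, clockwise from north).
#'
#' @param grid A [domain_grid()].
#' @param config A [synth_config()].
#' @return A list of class `fire_met` with the grid and arrays
#'   `wind`, `wind_dir`, `temp`, `rh`, `soil`, each `[365, n_rows, n_cols]`.
#' @export
generate_meteorology <- function(grid, config) {
  stopifnot(inherits(grid, "domain_grid"), inherits(config, "synth_config"))
  set.seed(config$seed + 101L)
  nr <- grid$n_rows; nc <- grid$n_cols
  season <- doy_season(1:365)
  mk <- function() array(0, dim = c(365, nr, nc))
  out <- list(wind = mk(), wind_dir = mk(), temp = mk(), rh = mk(),
              soil = mk())
  vars <- c(wind = "wind", wind_dir = "dir", temp = "temp", rh = "rh",
            soil = "soil")
  half <- sqrt(0.5)
  for (d in 1:365) {
    p <- config$met_params[[season[d]]]
    for (v in names(vars)) {
      pv <- p[[vars[[v]]]]
      zday <- rnorm(1)
      zcell <- smooth_field(matrix(rnorm(nr * nc), nr, nc))
      out[[v]][d, , ] <- pv[1] + pv[2] * (half * zday + half * zcell)
    }
  }
  out$wind <- pmax(out$wind, 0)
  out$rh <- pmin(pmax(out$rh, 0), 1)
  out$soil <- pmin(pmax(out$soil, 0), 1)
  out$wind_dir <- out$wind_dir %% 360
  structure(c(list(grid = grid), out), class = "fire_met")
}

#' @export
print.fire_met <- function(x, ...) {
  cat(sprintf("fire_met: 365 days on a %d x %d grid\n",
              x$grid$n_rows, x$grid$n_cols))
  cat(sprintf("  domain-mean wind %.2f m/s, temp %.1f C, RH %.2f, soil %.2f\n",
              mean(x$wind), mean(x$temp), mean(x$rh), mean(x$soil)))
  invisible(x)
}

#' Generate a year of fire events
#'
#' Ignition days follow the monthly `season_weights` (default concentrated
#' May-September); locations are uniform over the grid; burned areas are
#' lognormal with a heavy tail. Fires larger than the multi-day threshold are
#' split over consecutive days, occasionally spilling into an adjacent cell,
#' so the multi-day collapse rule of the scheduler is exercised.
#'
#' @param grid A [domain_grid()].
#' @param config A [synth_config()].
#' @return A data.frame of class `fire_events` with columns `event_id`,
#'   `day` (day-of-year), `row`, `col`, `area_km2`. One row per fire-day.
#' @export
generate_fires <- function(grid, config) {
  stopifnot(inherits(grid, "domain_grid"), inherits(config, "synth_config"))
  set.seed(config$seed + 202L)
  n <- config$n_fires
  empty <- data.frame(event_id = integer(), day = integer(), row = integer(),
                      col = integer(), area_km2 = numeric())
  if (n == 0) return(structure(empty, class = c("fire_events", "data.frame")))

  month <- sample.int(12, n, replace = TRUE, prob = config$season_weights)
  day <- mdy_doy(month, ceiling(runif(n) * .MONTH_DAYS[month]))
  row <- sample.int(grid$n_rows, n, replace = TRUE)
  col <- sample.int(grid$n_cols, n, replace = TRUE)
  area <- rlnorm(n, config$fire_size$meanlog, config$fire_size$sdlog)

  md <- config$multi_day
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (area[i] > md$threshold_km2) {
      ndays <- min(1L + floor(area[i] / md$threshold_km2), md$max_days,
                   365L - day[i] + 1L)
      ndays <- max(ndays, 1L)
      w <- runif(ndays) + 0.5 # avoid near-zero shares
      w <- w / sum(w)
      days_i <- day[i] + seq_len(ndays) - 1L
      rows_i <- rep(row[i], ndays); cols_i <- rep(col[i], ndays)
      if (ndays > 1 && runif(1) < md$p_spread) {
        # later days move one cell in a random cardinal direction
        step <- sample(list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)), 1)[[1]]
        r2 <- min(max(row[i] + step[1], 1L), grid$n_rows)
        c2 <- min(max(col[i] + step[2], 1L), grid$n_cols)
        half2 <- (ndays %/% 2 + 1):ndays
        rows_i[half2] <- r2; cols_i[half2] <- c2
      }
      rows[[i]] <- data.frame(event_id = i, day = days_i, row = rows_i,
                              col = cols_i, area_km2 = area[i] * w)
    } else {
      rows[[i]] <- data.frame(event_id = i, day = day[i], row = row[i],
                              col = col[i], area_km2 = area[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("fire_events", "data.frame"))
}

#' Generate a gridded population raster
#'
#' Population mass is distributed over Gaussian clusters whose centres sit in
#' the southern `south_frac` of the domain (mirroring a domain whose large
#' population centres lie south of the main fire activity), then rounded to
#' integers with largest-remainder redistribution so the configured total is
#' conserved exactly.
#'
#' @param grid A [domain_grid()].
#' @param config A [synth_config()].
#' @return An integer matrix `[n_rows, n_cols]` of person counts.
#' @export
generate_population <- function(grid, config) {
  stopifnot(inherits(grid, "domain_grid"), inherits(config, "synth_config"))
  set.seed(config$seed + 303L)
  p <- config$population
  nr <- grid$n_rows; nc <- grid$n_cols
  cc <- cell_centers(grid)
  max_row <- max(1L, round(p$south_frac * nr))
  dens <- numeric(nr * nc)
  for (k in seq_len(p$n_clusters)) {
    crow <- sample.int(max_row, 1)
    ccol <- sample.int(nc, 1)
    cx <- grid$origin[1] + (ccol - 0.5) * grid$cell_size
    cy <- grid$origin[2] + (crow - 0.5) * grid$cell_size
    if (p$dispersion_km == 0) {
      dens[cell_index(grid, crow, ccol)] <-
        dens[cell_index(grid, crow, ccol)] + 1
    } else {
      d2 <- (cc$x - cx)^2 + (cc$y - cy)^2
      dens <- dens + exp(-d2 / (2 * p$dispersion_km^2))
    }
  }
  target <- dens / sum(dens) * p$total
  base <- floor(target)
  remainder <- as.integer(round(p$total - sum(base)))
  if (remainder > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(remainder)]
    base[extra] <- base[extra] + 1
  }
  matrix(as.integer(base), nr, nc)
}

#' Generate per-cell fuel beds
#'
#' Each cell is assigned a dominant vegetation type (forest, shrubland,
#' grassland) by the configured probabilities, then the five loading
#' categories (canopy, shrub, nonwoody, woody, duff; kg/km2) are drawn
#' lognormally around the type's mean loadings.
#'
#' @param grid A [domain_grid()].
#' @param config A [synth_config()].
#' @return A data.frame of class `fuel_beds` with one row per cell: `row`,
#'   `col`, the five loading columns and the derived `cover_type`. Rows are
#'   in column-major cell order so `beds[cell_index(grid, r, c), ]` is the
#'   bed of cell (r, c).
#' @export
generate_fuelbeds <- function(grid, config) {
  stopifnot(inherits(grid, "domain_grid"), inherits(config, "synth_config"))
  set.seed(config$seed + 404L)
  f <- config$fuel
  ncell <- n_cells(grid)
  type <- sample(c("forest", "shrubland", "grassland"), ncell, replace = TRUE,
                 prob = c(f$p_forest, f$p_shrub, f$p_grass))
  cats <- c("canopy", "shrub", "nonwoody", "woody", "duff")
  loadings <- matrix(0, ncell, 5, dimnames = list(NULL, cats))
  for (cat in cats) {
    mu <- vapply(type, function(t) f[[t]][[cat]], numeric(1))
    noise <- rlnorm(ncell, -f$sdlog^2 / 2, f$sdlog) # mean-1 multiplier
    loadings[, cat] <- mu * noise
  }
  cc <- cell_centers(grid)
  beds <- data.frame(row = cc$row, col = cc$col, loadings)
  beds$cover_type <- classify_fuelbed(beds)
  structure(beds, class = c("fuel_beds", "data.frame"))
}

#' Generate synthetic station observations from a concentration field
#'
#' Places monitoring stations at random locations, samples the modeled field
#' at the nearest cell, adds a background level and multiplicative lognormal
#' noise. Purely synthetic: a stand-in for real monitor data so the
#' evaluation statistics can be exercised end-to-end.
#'
#' @param conc A `[365, n_rows, n_cols]` concentration array (ug/m3).
#' @param grid A [domain_grid()].
#' @param n_stations Number of stations.
#' @param seed RNG seed.
#' @param background Mean background PM2.5 added to the fire increment, ug/m3.
#' @param noise_sdlog Lognormal sdlog of the observational noise.
#' @return A data.frame with `station_id`, `x`, `y`, `day`, `pm25`.
#' @export
generate_observations <- function(conc, grid, n_stations = 10, seed = 1L,
                                  background = 5, noise_sdlog = 0.3) {
  stopifnot(inherits(grid, "domain_grid"), n_stations >= 1)
  set.seed(seed + 505L)
  ext_x <- grid$n_cols * grid$cell_size
  ext_y <- grid$n_rows * grid$cell_size
  x <- grid$origin[1] + runif(n_stations) * ext_x
  y <- grid$origin[2] + runif(n_stations) * ext_y
  stations <- data.frame(station_id = sprintf("S%02d", seq_len(n_stations)),
                         x = x, y = y)
  matched <- match_stations(stations, grid)
  out <- do.call(rbind, lapply(seq_len(nrow(matched)), function(i) {
    truth <- conc[, matched$row[i], matched$col[i]] + background
    noise <- rlnorm(365, -noise_sdlog^2 / 2, noise_sdlog)
    data.frame(station_id = matched$station_id[i], x = matched$x[i],
               y = matched$y[i], day = 1:365, pm25 = truth * noise)
  }))
  rownames(out) <- NULL
  out
}
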