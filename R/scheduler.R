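#' Prescribed-burn window criteria
#'
#' The meteorological window within which a day qualifies for prescribed
#' burning: 20-ft wind below 5.36 m/s (12 mph), temperature below 29.5 C
#' (85 F), relative humidity between 0.25 and 0.45, and soil moisture
#' between 0.15 and 0.3 m3/m3. When no day in the spring/fall seasons passes
#' the strict window for a fire's cell, a fallback tier relaxes wind to
#' below 6.7056 m/s (15 mph) and the RH upper bound to 0.6, retaining the
#' temperature and soil-moisture bounds and the RH lower bound.
#'
#' @param max_wind Strict wind bound, m/s.
#' @param max_temp Strict temperature bound, deg C.
#' @param rh_range Strict relative-humidity range (fractions).
#' @param soil_moisture_range Strict soil-moisture range, m3/m3.
#' @param fallback_max_wind Fallback wind bound, m/s (15 mph).
#' @param fallback_rh_max Fallback RH upper bound.
#' @return A list of class `burn_window_criteria`.
#' @export
burn_window_criteria <- function(max_wind = 5.36,
                                 max_temp = 29.5,
                                 rh_range = c(0.25, 0.45),
                                 soil_moisture_range = c(0.15, 0.3),
                                 fallback_max_wind = 6.7056,
                                 fallback_rh_max = 0.6) {
  stopifnot(rh_range[1] <= rh_range[2],
            soil_moisture_range[1] <= soil_moisture_range[2],
            fallback_max_wind >= max_wind,
            fallback_rh_max >= rh_range[2])
  structure(list(max_wind = max_wind, max_temp = max_temp,
                 rh_range = rh_range,
                 soil_moisture_range = soil_moisture_range,
                 fallback_max_wind = fallback_max_wind,
                 fallback_rh_max = fallback_rh_max),
            class = "burn_window_criteria")
}

#' A "no burn" calendar of excluded date intervals
#'
#' @param intervals A two-column matrix or data.frame of day-of-year
#'   `start`, `end` pairs (inclusive), or `NULL` for an empty calendar.
#' @return A list of class `no_burn_calendar` with the intervals and the
#'   expanded day set.
#' @export
no_burn_calendar <- function(intervals = NULL) {
  if (is.null(intervals) || NROW(intervals) == 0) {
    return(structure(list(intervals = data.frame(start = integer(),
                                                 end = integer()),
                          days = integer()),
                     class = "no_burn_calendar"))
  }
  intervals <- as.data.frame(intervals)
  names(intervals)[1:2] <- c("start", "end")
  stopifnot(all(intervals$start >= 1), all(intervals$end <= 365),
            all(intervals$start <= intervals$end))
  days <- sort(unique(unlist(Map(seq, intervals$start, intervals$end))))
  structure(list(intervals = intervals, days = as.integer(days)),
            class = "no_burn_calendar")
}

#' The fixed 2012 study no-burn periods
#'
#' April 27 - May 2, May 28 - June 2, October 26-28 and November 2-5:
#' the preset high-exposure periods excluded under the exposure-optimized
#' scenario. [screen_high_exposure_days()] is the general mechanism for
#' deriving such a calendar from a forecast.
#' @return A [no_burn_calendar()].
#' @export
no_burn_2012 <- function() {
  no_burn_calendar(rbind(
    c(mdy_doy(4, 27), mdy_doy(5, 2)),
    c(mdy_doy(5, 28), mdy_doy(6, 2)),
    c(mdy_doy(10, 26), mdy_doy(10, 28)),
    c(mdy_doy(11, 2), mdy_doy(11, 5))
  ))
}

# strict / fallback day filters over vectors of cell meteorology
.passes_strict <- function(wind, temp, rh, soil, cr) {
  wind < cr$max_wind & temp < cr$max_temp &
    rh >= cr$rh_range[1] & rh <= cr$rh_range[2] &
    soil >= cr$soil_moisture_range[1] & soil <= cr$soil_moisture_range[2]
}

.passes_fallback <- function(wind, temp, rh, soil, cr) {
  wind < cr$fallback_max_wind & temp < cr$max_temp &
    rh >= cr$rh_range[1] & rh <= cr$fallback_rh_max &
    soil >= cr$soil_moisture_range[1] & soil <= cr$soil_moisture_range[2]
}

#' Candidate prescribed-burn days for one fire
#'
#' Spring/fall days (minus any no-burn calendar days) whose meteorology in
#' the fire's grid cell satisfies the strict burn window, ordered by
#' ascending wind speed (ties: earliest date).
#'
#' @param fire A list or one-row data.frame with `row` and `col`.
#' @param met A `fire_met` object covering the fire's cell.
#' @param criteria A [burn_window_criteria()].
#' @param no_burn A [no_burn_calendar()] (empty by default).
#' @return Data.frame with columns `day`, `wind_ms`, sorted by wind speed.
#'   Zero rows if no day qualifies.
#' @export
candidate_days <- function(fire, met, criteria = burn_window_criteria(),
                           no_burn = no_burn_calendar()) {
  days <- setdiff(burn_season_days(), no_burn$days)
  r <- fire$row[1]; c <- fire$col[1]
  wind <- met$wind[days, r, c]
  ok <- .passes_strict(wind, met$temp[days, r, c], met$rh[days, r, c],
                       met$soil[days, r, c], criteria)
  days <- days[ok]; wind <- wind[ok]
  ord <- order(wind, days)
  data.frame(day = days[ord], wind_ms = wind[ord])
}

#' Assign a prescribed-burn day to a fire
#'
#' Chooses the minimum-wind strict-window day; if none exists, the
#' minimum-wind fallback-tier day (wind < 15 mph, RH up to 0.6). Equal wind
#' speeds break to the earliest date. Errors, naming the fire, if not even
#' the fallback tier contains a day.
#'
#' @inheritParams candidate_days
#' @return A list with `day` (day-of-year) and `tier`
#'   (`"strict"` or `"fallback"`).
#' @export
assign_day <- function(fire, met, criteria = burn_window_criteria(),
                       no_burn = no_burn_calendar()) {
  cd <- candidate_days(fire, met, criteria, no_burn)
  if (nrow(cd) > 0) return(list(day = cd$day[1], tier = "strict"))
  days <- setdiff(burn_season_days(), no_burn$days)
  r <- fire$row[1]; c <- fire$col[1]
  wind <- met$wind[days, r, c]
  ok <- .passes_fallback(wind, met$temp[days, r, c], met$rh[days, r, c],
                         met$soil[days, r, c], criteria)
  if (!any(ok)) {
    id <- if (!is.null(fire$event_id)) fire$event_id[1] else NA
    stop(sprintf(
      "no candidate burn day (even fallback tier) for fire event %s at cell (%d, %d)",
      id, r, c))
  }
  days <- days[ok]; wind <- wind[ok]
  ord <- order(wind, days)
  list(day = days[ord[1]], tier = "fallback")
}

#' Collapse multi-day fire events confined to one grid cell
#'
#' A fire that burned over consecutive days entirely within a single grid
#' cell can be burned on a single day under prescribed conditions: its
#' per-day areas are summed into one record (dated at the first day).
#' Events spanning multiple cells are left as independent per-row fires.
#'
#' @param fires A `fire_events` data.frame with `event_id`.
#' @return A `fire_events` data.frame with an added logical `collapsed`.
#' @export
collapse_multiday <- function(fires) {
  if (nrow(fires) == 0) {
    fires$collapsed <- logical(0)
    return(fires)
  }
  pieces <- lapply(split(fires, fires$event_id), function(ev) {
    one_cell <- length(unique(ev$row)) == 1 && length(unique(ev$col)) == 1
    d <- sort(ev$day)
    consecutive <- length(d) == 1 || all(diff(d) == 1)
    if (nrow(ev) > 1 && one_cell && consecutive) {
      out <- ev[1, , drop = FALSE]
      out$day <- min(ev$day)
      out$area_km2 <- sum(ev$area_km2)
      out$collapsed <- TRUE
      out
    } else {
      ev$collapsed <- FALSE
      ev
    }
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$event_id, out$day), ]
  rownames(out) <- NULL
  structure(out, class = c("fire_events", "data.frame"))
}

#' Re-schedule all fires onto prescribed-burn days
#'
#' Collapses single-cell multi-day events, then assigns each fire the
#' minimum-wind qualifying spring/fall day ([assign_day()]). Mode `"rx2"`
#' additionally excludes the days of a no-burn calendar before the same
#' meteorological filters are applied. Burned area is conserved exactly.
#'
#' @param fires A `fire_events` data.frame.
#' @param met A `fire_met` object.
#' @param criteria A [burn_window_criteria()].
#' @param mode `"rx1"` (meteorology only) or `"rx2"` (also avoids the
#'   no-burn calendar).
#' @param no_burn A [no_burn_calendar()]; required for mode `"rx2"`.
#' @return A list of class `schedule_result`: `schedule` (data.frame with
#'   `fire_id`, `event_id`, `row`, `col`, `area_km2`, `orig_day`, `day`,
#'   `tier`, `collapsed`), `fires` (the re-dated `fire_events`),
#'   `fallback_area_frac` (fraction of total burned area placed by the
#'   fallback tier) and `mode`.
#' @export
build_scenario <- function(fires, met, criteria = burn_window_criteria(),
                           mode = c("rx1", "rx2"),
                           no_burn = no_burn_calendar()) {
  mode <- match.arg(mode)
  cal <- if (mode == "rx2") no_burn else no_burn_calendar()
  fires <- collapse_multiday(fires)
  n <- nrow(fires)
  day <- integer(n); tier <- character(n)
  for (i in seq_len(n)) {
    a <- assign_day(fires[i, ], met, criteria, cal)
    day[i] <- a$day; tier[i] <- a$tier
  }
  schedule <- data.frame(fire_id = seq_len(n), event_id = fires$event_id,
                         row = fires$row, col = fires$col,
                         area_km2 = fires$area_km2, orig_day = fires$day,
                         day = day, tier = tier,
                         collapsed = fires$collapsed)
  new_fires <- fires
  new_fires$day <- day
  total <- sum(fires$area_km2)
  fb <- if (total > 0) sum(fires$area_km2[tier == "fallback"]) / total else 0
  structure(list(schedule = schedule, fires = new_fires,
                 fallback_area_frac = fb, mode = mode),
            class = "schedule_result")
}

#' @export
print.schedule_result <- function(x, ...) {
  cat(sprintf(
    "schedule_result (%s): %d fires, %.4g km2, %.1f%% of area via fallback tier\n",
    x$mode, nrow(x$schedule), sum(x$schedule$area_km2),
    100 * x$fallback_area_frac))
  invisible(x)
}

#' Derive a no-burn calendar by screening forecast exposure
#'
#' For each spring/fall day, forecasts the population-weighted PM2.5 that
#' would result if every pending fire emitted a unit mass in its cell on
#' that day (single-day surrogate transport under that day's winds,
#' prescribed-burn mixing depth), then excludes the days whose forecast
#' exceeds the given quantile of the distribution.
#'
#' @param fires A `fire_events` data.frame (each row contributes one unit
#'   source at its cell).
#' @param met A `fire_met` object.
#' @param population Population matrix `[n_rows, n_cols]`.
#' @param params A [surrogate_params()].
#' @param quantile_cut Quantile above which days are excluded; default 0.9.
#'   `quantile_cut = 1` excludes nothing.
#' @return A [no_burn_calendar()] of the excluded days, with the forecast
#'   series attached as attribute `"forecast"` (data.frame `day`, `pw`).
#' @export
screen_high_exposure_days <- function(fires, met, population,
                                      params = surrogate_params(),
                                      quantile_cut = 0.9) {
  stopifnot(quantile_cut >= 0, quantile_cut <= 1)
  grid <- met$grid
  days <- burn_season_days()
  src <- matrix(0, grid$n_rows, grid$n_cols)
  if (nrow(fires) > 0) {
    idx <- cell_index(grid, fires$row, fires$col)
    tab <- table(idx)
    src[as.integer(names(tab))] <- as.numeric(tab)
  }
  depth <- params$mixing_depth[["rx"]]
  pw <- vapply(days, function(d) {
    a <- transport_step(src, met$wind[d, , ], met$wind_dir[d, , ], grid,
                        params)
    conc <- mass_to_conc(a, grid, depth)
    population_weighted(conc, population)
  }, numeric(1))
  cut <- quantile(pw, quantile_cut, names = FALSE, type = 7)
  excl <- days[pw > cut]
  cal <- if (length(excl) == 0) {
    no_burn_calendar()
  } else {
    # contiguous excluded days become intervals
    brk <- c(0, which(diff(excl) != 1), length(excl))
    iv <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
      c(excl[brk[i] + 1], excl[brk[i + 1]])
    }))
    no_burn_calendar(iv)
  }
  attr(cal, "forecast") <- data.frame(day = days, pw = pw)
  cal
}
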