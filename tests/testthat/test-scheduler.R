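test_that("criteria constructor validates its bounds", {
  cr <- burn_window_criteria()
  expect_equal(cr$max_wind, 5.36)
  expect_equal(cr$fallback_max_wind, 6.7056)
  expect_error(burn_window_criteria(fallback_max_wind = 4), "not TRUE")
  expect_error(burn_window_criteria(rh_range = c(0.5, 0.4)), "not TRUE")
})

test_that("candidate days: hand-written fixture, wind ordering, no-burn exclusion", {
  g <- tiny_grid(3, 3)
  met <- constant_met(g, wind = 9, temp = 20, rh = 0.35, soil = 0.2)
  fire <- data.frame(event_id = 1, day = 200, row = 2, col = 2,
                     area_km2 = 1)
  # all days fail the strict window (wind too high) -> empty
  expect_equal(nrow(candidate_days(fire, met)), 0)

  # five hand-written spring days, two passing, lowest wind first
  d <- mdy_doy(4, 1:5)
  met$wind[d, 2, 2] <- c(3.0, 9.0, 2.1, 5.36, 4.0)
  met$rh[d, 2, 2] <- c(0.30, 0.30, 0.40, 0.30, 0.80)
  cd <- candidate_days(fire, met)
  expect_equal(cd$day, c(d[3], d[1])) # winds 2.1 then 3.0
  expect_equal(cd$wind_ms, c(2.1, 3.0))

  # a passing day inside a no-burn interval is excluded only with the calendar
  cal <- no_burn_calendar(cbind(d[3], d[3]))
  expect_equal(candidate_days(fire, met, no_burn = cal)$day, d[1])
  expect_true(d[3] %in% candidate_days(fire, met)$day)
})

test_that("day assignment: minimum wind, date tie-break, fallback tier, hard failure", {
  g <- tiny_grid(3, 3)
  fire <- data.frame(event_id = 7, day = 200, row = 1, col = 1, area_km2 = 1)
  met <- constant_met(g, wind = 9)
  d <- mdy_doy(9, 10:12)

  met$wind[d, 1, 1] <- c(3.0, 2.1, 2.1)
  a <- assign_day(fire, met)
  expect_equal(a$day, d[2]) # lowest wind, earliest date among the 2.1 tie
  expect_equal(a$tier, "strict")

  # no strict day anywhere, one fallback day (wind < 15 mph, RH up to 0.6)
  met2 <- constant_met(g, wind = 9, rh = 0.55)
  met2$wind[d[1], 1, 1] <- 6.0
  a2 <- assign_day(fire, met2)
  expect_equal(a2$day, d[1])
  expect_equal(a2$tier, "fallback")

  # nothing qualifies even under the fallback tier
  met3 <- constant_met(g, wind = 9)
  expect_error(assign_day(fire, met3), "fire event 7")
})

test_that("multi-day collapse merges single-cell consecutive events only", {
  fires <- structure(data.frame(
    event_id = c(1, 1, 1, 2, 2, 3),
    day = c(150, 151, 152, 160, 161, 170),
    row = c(4, 4, 4, 2, 3, 5),
    col = c(4, 4, 4, 2, 2, 1),
    area_km2 = c(1, 2, 3, 5, 5, 2)
  ), class = c("fire_events", "data.frame"))
  out <- collapse_multiday(fires)
  ev1 <- out[out$event_id == 1, ]
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$area_km2, 6)
  expect_equal(ev1$day, 150)
  expect_true(ev1$collapsed)
  expect_equal(nrow(out[out$event_id == 2, ]), 2) # two cells: not merged
  expect_false(any(out$collapsed[out$event_id == 2]))
  expect_equal(out[out$event_id == 3, "area_km2"], 2) # single day unchanged
  expect_equal(sum(out$area_km2), sum(fires$area_km2))
})

test_that("scheduling matches exhaustive search and conserves burned area", {
  g <- tiny_grid(8, 8)
  met <- random_met(g, seed = 31)
  cfg <- synth_config(seed = 31, n_fires = 50)
  fires <- generate_fires(g, cfg)
  fires$row <- pmin(fires$row, 8); fires$col <- pmin(fires$col, 8)
  cr <- burn_window_criteria()
  res <- build_scenario(fires, met, cr, mode = "rx1")
  collapsed <- collapse_multiday(fires)

  # exhaustive-search oracle: filter all days, min wind, tie-break by date
  season <- burn_season_days()
  for (i in seq_len(nrow(collapsed))) {
    r <- collapsed$row[i]; c <- collapsed$col[i]
    ok <- brute_force_strict(met, r, c, season, cr)
    cand <- season[ok]; w <- met$wind[season, r, c][ok]
    if (length(cand) > 0) {
      best <- cand[w == min(w)][1]
      expect_equal(res$schedule$day[i], best)
      expect_equal(res$schedule$tier[i], "strict")
    } else {
      expect_equal(res$schedule$tier[i], "fallback")
    }
  }

  # conservation, seasonality, feasibility re-check
  expect_identical(sum(res$fires$area_km2), sum(fires$area_km2))
  expect_true(all(doy_season(res$schedule$day) %in% c("spring", "fall")))
  for (i in seq_len(nrow(res$schedule))) {
    s <- res$schedule[i, ]
    if (s$tier == "strict") {
      expect_true(brute_force_strict(met, s$row, s$col, s$day, cr))
    } else {
      expect_true(met$wind[s$day, s$row, s$col] < cr$fallback_max_wind)
      expect_true(met$rh[s$day, s$row, s$col] <= cr$fallback_rh_max)
    }
  }
})

test_that("the no-burn calendar only removes candidates (rx2 subset of rx1)", {
  g <- tiny_grid(6, 6)
  met <- random_met(g, seed = 17)
  cal <- no_burn_2012()
  for (i in 1:20) {
    fire <- data.frame(event_id = i, day = 150,
                       row = sample.int(6, 1), col = sample.int(6, 1),
                       area_km2 = 1)
    c1 <- candidate_days(fire, met)$day
    c2 <- candidate_days(fire, met, no_burn = cal)$day
    expect_true(all(c2 %in% c1))
    expect_false(any(c2 %in% cal$days))
  }
})

test_that("rx2 re-assigns exactly the fires whose rx1 day is embargoed", {
  g <- tiny_grid(8, 8)
  met <- random_met(g, seed = 53)
  cfg <- synth_config(seed = 53, n_fires = 40)
  fires <- generate_fires(g, cfg)
  fires$row <- pmin(fires$row, 8); fires$col <- pmin(fires$col, 8)
  rx1 <- build_scenario(fires, met, mode = "rx1")
  # embargo the most popular rx1 day
  top_day <- as.integer(names(sort(table(rx1$schedule$day),
                                   decreasing = TRUE))[1])
  cal <- no_burn_calendar(cbind(top_day, top_day))
  rx2 <- build_scenario(fires, met, mode = "rx2", no_burn = cal)
  moved <- rx1$schedule$day != rx2$schedule$day
  expect_true(all(rx1$schedule$day[moved] == top_day))
  expect_false(any(rx2$schedule$day == top_day))
  expect_identical(rx2$schedule$day[!moved], rx1$schedule$day[!moved])
})

test_that("exposure screening excludes exactly the forecast-dominant days", {
  g <- tiny_grid(5, 5)
  met <- constant_met(g, wind = 0)
  pop <- matrix(0L, 5, 5); pop[3, 5] <- 1000L # everyone two cells east
  fires <- data.frame(event_id = 1, day = 200, row = 3, col = 3,
                      area_km2 = 1)
  # displacement of exactly 2 cells: scale * wind * 86.4 / cell = 2
  params <- surrogate_params(diffusion_km = 0, advection_scale = 0.2)
  hit_wind <- 2 * g$cell_size / (86.4 * params$advection_scale)
  hot <- mdy_doy(4, c(3, 10, 20)) # three spring days aimed at the people
  met$wind[hot, , ] <- hit_wind
  met$wind_dir[hot, , ] <- 90 # toward east

  cal <- screen_high_exposure_days(fires, met, pop, params,
                                   quantile_cut = 0.9)
  expect_setequal(cal$days, hot)

  # q = 1 excludes nothing
  cal1 <- screen_high_exposure_days(fires, met, pop, params,
                                    quantile_cut = 1)
  expect_equal(length(cal1$days), 0)
})

test_that("the preset 2012 no-burn periods cover the stated dates", {
  cal <- no_burn_2012()
  expect_true(mdy_doy(4, 27) %in% cal$days)
  expect_true(mdy_doy(5, 2) %in% cal$days)
  expect_true(mdy_doy(6, 2) %in% cal$days)
  expect_true(mdy_doy(10, 27) %in% cal$days)
  expect_true(mdy_doy(11, 5) %in% cal$days)
  expect_false(mdy_doy(5, 3) %in% cal$days)
  expect_equal(length(cal$days), 6 + 6 + 3 + 4)
})
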