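test_that("all generators are bit-identical under a fixed seed", {
  g <- tiny_grid(8, 8)
  cfg <- synth_config(seed = 42, n_fires = 60)
  expect_identical(generate_meteorology(g, cfg), generate_meteorology(g, cfg))
  expect_identical(generate_fires(g, cfg), generate_fires(g, cfg))
  expect_identical(generate_population(g, cfg), generate_population(g, cfg))
  expect_identical(generate_fuelbeds(g, cfg), generate_fuelbeds(g, cfg))
})

test_that("meteorology respects physical ranges and seasonal burn-window structure", {
  g <- domain_grid(20, 20)
  met <- generate_meteorology(g, synth_config(seed = 7))
  expect_true(all(met$wind >= 0))
  expect_true(all(met$rh >= 0 & met$rh <= 1))
  expect_true(all(met$soil >= 0 & met$soil <= 1))
  expect_true(all(met$wind_dir >= 0 & met$wind_dir < 360))

  # independent filter count: April strict-window fraction
  cr <- burn_window_criteria()
  pass <- met$wind < cr$max_wind & met$temp < cr$max_temp &
    met$rh >= cr$rh_range[1] & met$rh <= cr$rh_range[2] &
    met$soil >= cr$soil_moisture_range[1] &
    met$soil <= cr$soil_moisture_range[2]
  april <- doy_month(1:365) == 4
  expect_gte(mean(pass[april, , ]), 0.3)
  expect_lte(mean(pass[april, , ]), 1.0)
  summer <- doy_season(1:365) == "summer"
  expect_lt(mean(pass[summer, , ]), 0.05)
})

test_that("zero-variance meteorology is constant within a season", {
  g <- tiny_grid(4, 4)
  mp <- default_met_params()
  for (s in names(mp)) for (v in names(mp[[s]])) mp[[s]][[v]][2] <- 0
  met <- generate_meteorology(g, synth_config(seed = 1, met_params = mp))
  spring <- which(doy_season(1:365) == "spring")
  for (v in c("wind", "temp", "rh", "soil", "wind_dir"))
    expect_equal(length(unique(as.vector(met[[v]][spring, , ]))), 1)
})

test_that("fire generation: empty case, positivity, season weights, analytic mean", {
  g <- domain_grid(20, 20)
  expect_equal(nrow(generate_fires(g, synth_config(seed = 1, n_fires = 0))), 0)

  cfg <- synth_config(seed = 11, n_fires = 500)
  fires <- generate_fires(g, cfg)
  expect_true(all(fires$area_km2 > 0))
  expect_true(all(fires$day >= 1 & fires$day <= 365))
  expect_true(all(fires$row >= 1 & fires$row <= 20))
  # total area within +-50% of n * closed-form lognormal mean
  mean_size <- exp(cfg$fire_size$meanlog + cfg$fire_size$sdlog^2 / 2)
  expect_gt(sum(fires$area_km2), 0.5 * 500 * mean_size)
  expect_lt(sum(fires$area_km2), 1.5 * 500 * mean_size)
  # ignitions concentrated May-September under the default weights
  first_day <- tapply(fires$day, fires$event_id, min)
  expect_gt(mean(doy_month(first_day) %in% 5:9), 0.6)
})

test_that("population conserves the configured total exactly and supports degenerate clusters", {
  g <- tiny_grid(10, 10)
  cfg <- synth_config(seed = 3,
                      population = list(n_clusters = 3L, total = 1e6,
                                        dispersion_km = 30, south_frac = 0.4))
  pop <- generate_population(g, cfg)
  expect_identical(sum(pop), 1000000L)
  expect_true(all(pop >= 0))

  one <- synth_config(seed = 3,
                      population = list(n_clusters = 1L, total = 12345,
                                        dispersion_km = 0, south_frac = 0.4))
  pop1 <- generate_population(g, one)
  expect_identical(sum(pop1), 12345L)
  expect_equal(sum(pop1 > 0), 1)
})

test_that("fuel beds span all three cover types; degenerate config collapses to one", {
  g <- domain_grid(20, 20)
  beds <- generate_fuelbeds(g, synth_config(seed = 5))
  expect_true(all(beds[, c("canopy", "shrub", "nonwoody", "woody",
                           "duff")] >= 0))
  expect_setequal(unique(beds$cover_type),
                  c("forest", "shrubland", "grassland"))
  expect_identical(beds$cover_type, classify_fuelbed(beds))

  cfg <- synth_config(seed = 5)
  cfg$fuel$p_forest <- 1; cfg$fuel$p_shrub <- 0; cfg$fuel$p_grass <- 0
  forest_only <- generate_fuelbeds(g, cfg)
  expect_true(all(forest_only$cover_type == "forest"))
})

test_that("the default generator leaves almost no fire without a strict-window day", {
  g <- domain_grid(20, 20)
  cfg <- synth_config(seed = 9, n_fires = 100)
  met <- generate_meteorology(g, cfg)
  fires <- collapse_multiday(generate_fires(g, cfg))
  has_strict <- vapply(seq_len(nrow(fires)), function(i)
    nrow(candidate_days(fires[i, ], met)) > 0, logical(1))
  expect_gte(mean(has_strict), 0.9)
})
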