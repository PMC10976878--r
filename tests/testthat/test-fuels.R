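test_that("fuel-bed classification follows the dominant loading share", {
  expect_equal(classify_fuelbed(data.frame(canopy = 40, woody = 30,
                                           shrub = 20, nonwoody = 10)),
               "forest")
  expect_equal(classify_fuelbed(data.frame(canopy = 15, woody = 15,
                                           shrub = 60, nonwoody = 10)),
               "shrubland")
  expect_equal(classify_fuelbed(data.frame(canopy = 20, woody = 0,
                                           shrub = 30, nonwoody = 50)),
               "grassland")
  # ties break forest > shrubland > grassland
  expect_equal(classify_fuelbed(data.frame(canopy = 25, woody = 25,
                                           shrub = 50, nonwoody = 50)),
               "forest")
  expect_equal(classify_fuelbed(data.frame(canopy = 0, woody = 0,
                                           shrub = 50, nonwoody = 50)),
               "shrubland")
  expect_error(classify_fuelbed(data.frame(canopy = 0, woody = 0,
                                           shrub = 0, nonwoody = 0)),
               "all-zero")
  # duff plays no role in the comparison
  expect_equal(classify_fuelbed(data.frame(canopy = 1, woody = 1, shrub = 10,
                                           nonwoody = 1, duff = 100)),
               "shrubland")
})

test_that("soil-to-fuel moisture map is linear on the configured range", {
  expect_equal(fuel_moisture_from_soil(0, c(0.05, 0.40)), 0.05)
  expect_equal(fuel_moisture_from_soil(1, c(0.05, 0.40)), 0.40)
  expect_equal(fuel_moisture_from_soil(0.5, c(0.1, 0.3)), 0.2)
  expect_error(fuel_moisture_from_soil(1.2), "\\[0, 1\\]")
  expect_error(fuel_moisture_from_soil(-0.1), "\\[0, 1\\]")
})

test_that("consumption implements the canopy/shrub rules and moisture monotonicity", {
  bed <- data.frame(canopy = 2e5, shrub = 1e5, nonwoody = 5e4, woody = 3e5,
                    duff = 2e5)
  rx <- consume_fuels(bed, 0.2, "rx")
  expect_equal(rx$canopy, 0)
  wf <- consume_fuels(bed, 0.2, "wildfire")
  expect_equal(wf$canopy, 1e5) # 50% of canopy under wildfire conditions
  expect_equal(wf$shrub, 5e4)  # 50% blackened, both fire types
  expect_equal(rx$shrub, 5e4)

  # surface consumption non-increasing in fuel moisture (brute-force scan)
  m <- seq(0, 1, by = 0.01)
  tot <- consume_fuels(bed[rep(1, length(m)), ], m, "wildfire")$total
  expect_true(all(diff(tot) <= 1e-9))
  # at maximum moisture the surface fraction hits its configured minimum
  wet <- consume_fuels(bed, 1, "wildfire", consume_params())
  expect_equal(wet$woody, 0.3 * 3e5)
})

test_that("consumption never exceeds loading and the smoldering split is exact", {
  beds <- random_beds(2000, seed = 21)
  m <- runif(2000)
  for (ft in c("wildfire", "rx")) {
    cons <- consume_fuels(beds, m, ft)
    for (cat in c("canopy", "shrub", "nonwoody", "woody", "duff")) {
      expect_true(all(cons[[cat]] >= 0))
      expect_true(all(cons[[cat]] <= beds[[cat]] + 1e-9))
    }
    expect_equal(cons$stfs_total + cons$rsc_woody + cons$rsc_duff,
                 cons$total, tolerance = 1e-12)
  }
})

test_that("emission masses follow burned area x consumption x emission factor", {
  ef <- default_ef_table()
  stfs_only <- data.frame(stfs_total = 5e5, rsc_woody = 0, rsc_duff = 0)
  expect_equal(compute_emissions(2, stfs_only, "forest", "rx", ef),
               2 * 5e5 * 17.57)
  wf <- compute_emissions(2, stfs_only, "forest", "wildfire", ef)
  expect_equal(wf, 2 * 5e5 * 23.2)
  expect_gt(wf, compute_emissions(2, stfs_only, "forest", "rx", ef))

  expect_equal(compute_emissions(0, stfs_only, "forest", "wildfire", ef), 0)

  # residual smoldering uses the woody/duff RSC factors
  rsc <- data.frame(stfs_total = 0, rsc_woody = 1e4, rsc_duff = 2e4)
  expect_equal(compute_emissions(1, rsc, "grassland", "rx", ef),
               1e4 * 33 + 2e4 * 35.3)

  expect_error(compute_emissions(1, stfs_only, "forest", "rx", ef,
                                 species = "CO"),
               "no emission factor")
})

test_that("emissions are linear in burned area and in consumption", {
  ef <- default_ef_table()
  cons <- data.frame(stfs_total = 3.3e5, rsc_woody = 2e4, rsc_duff = 5e4)
  base <- compute_emissions(1.7, cons, "forest", "wildfire", ef)
  expect_identical(compute_emissions(3.4, cons, "forest", "wildfire", ef),
                   2 * base)
  expect_identical(compute_emissions(1.7, cons * 3, "forest", "wildfire", ef),
                   3 * base)
})

test_that("inventory summary computes totals, bracketsed reductions and the 1-tonne day count", {
  mk_inv <- function(mass_g, day = c(10, 200)) {
    structure(data.frame(fire_id = 1:2, event_id = 1:2, day = day,
                         row = 1, col = 1, area_km2 = c(2, 3),
                         cover_type = "forest", fuel_moisture = 0.2,
                         consumption_kg = c(4e9, 6e9), species = "PM25",
                         mass_g = mass_g),
              class = c("emission_inventory", "data.frame"))
  }
  invs <- list(wildfire = mk_inv(c(2e11, 0.65e11)),
               rx = mk_inv(c(1e11, 0.38e11)))
  s <- summarize_inventory(invs, baseline = "wildfire")
  expect_equal(s$totals$value[s$totals$scenario == "wildfire" &
                              s$totals$variable == "species_Tg"], 0.265)
  expect_equal(s$reduction_pct["species_Tg", "rx"], 48)
  expect_equal(s$reduction_pct["burned_area_km2", "rx"], 0)
  expect_equal(unname(s$days_over_1t["wildfire"]), 2)
  expect_equal(sum(s$daily[, "wildfire"]), 2.65e11)

  # identical scenarios -> 0% everywhere
  same <- summarize_inventory(list(a = invs$wildfire, b = invs$wildfire),
                              baseline = "a")
  expect_true(all(same$reduction_pct == 0))

  # zero baseline guards the division
  zero <- mk_inv(c(0, 0)); zero$consumption_kg <- c(0, 0)
  zero$area_km2 <- c(0, 0)
  g <- summarize_inventory(list(base = zero, rx = invs$rx),
                           baseline = "base")
  expect_true(all(is.na(g$reduction_pct)))
})
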