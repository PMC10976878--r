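#' Classify a fuel bed into forest, shrubland or grassland
#'
#' Cover type follows the dominant loading share among canopy+woody
#' (forest), shrub (shrubland) and nonwoody (grassland). Duff does not enter
#' the comparison. Ties break by precedence forest > shrubland > grassland.
#'
#' @param bed A data.frame (or single named list/vector) with loading columns
#'   `canopy`, `shrub`, `nonwoody`, `woody` (kg/km2). Vectorized over rows.
#' @return Character vector of cover types.
#' @examples
#' classify_fuelbed(data.frame(canopy = 40, woody = 30, shrub = 20,
#'                             nonwoody = 10))
#' @export
classify_fuelbed <- function(bed) {
  bed <- as.data.frame(as.list(bed))[, c("canopy", "shrub", "nonwoody",
                                         "woody")]
  if (any(bed < 0)) stop("fuel loadings must be non-negative")
  shares <- cbind(forest = bed$canopy + bed$woody,
                  shrubland = bed$shrub,
                  grassland = bed$nonwoody)
  if (any(rowSums(shares) == 0))
    stop("cannot classify a fuel bed with all-zero loadings")
  # max.col with ties.method "first": column order encodes the precedence
  c("forest", "shrubland", "grassland")[max.col(shares, ties.method = "first")]
}

#' Map soil moisture to fuel moisture
#'
#' A monotone (by default linear) map from volumetric soil moisture onto a
#' configurable fuel-moisture range, standing in for the soil-moisture based
#' fuel-moisture estimate used in operational smoke modelling frameworks.
#'
#' @param soil_moisture Soil moisture, m3/m3 in \[0, 1\]. Vectorized.
#' @param range Length-2 numeric, fuel moisture at soil moisture 0 and 1.
#' @return Fuel moisture fraction(s) in `range`.
#' @export
fuel_moisture_from_soil <- function(soil_moisture, range = c(0.05, 0.40)) {
  if (any(soil_moisture < 0 | soil_moisture > 1))
    stop("soil moisture must be in [0, 1]")
  stopifnot(length(range) == 2, range[2] >= range[1])
  range[1] + (range[2] - range[1]) * soil_moisture
}

#' Consumption parameters
#'
#' @param canopy_frac Named fractions of canopy load consumed by fire type;
#'   defaults 0.5 for wildfire, 0 for prescribed burns.
#' @param shrub_blackened Fraction of shrub load blackened (consumed), both
#'   fire types. Default 0.5.
#' @param surface_frac Length-2 numeric: fraction of surface fuels (nonwoody,
#'   woody, duff) consumed at fuel moisture 0 and at fuel moisture 1; linear
#'   in between, so consumption decreases with moisture.
#' @param rsc_woody_frac Fraction of consumed woody fuel assigned to residual
#'   smoldering combustion (RSC). Default 0.3.
#' @param rsc_duff_frac Fraction of consumed duff assigned to RSC. Default 1.
#' @return A list of class `consume_params`.
#' @export
consume_params <- function(canopy_frac = c(wildfire = 0.5, rx = 0),
                           shrub_blackened = 0.5,
                           surface_frac = c(0.9, 0.3),
                           rsc_woody_frac = 0.3,
                           rsc_duff_frac = 1.0) {
  stopifnot(all(canopy_frac >= 0 & canopy_frac <= 1),
            shrub_blackened >= 0, shrub_blackened <= 1,
            length(surface_frac) == 2,
            all(surface_frac >= 0 & surface_frac <= 1),
            rsc_woody_frac >= 0, rsc_woody_frac <= 1,
            rsc_duff_frac >= 0, rsc_duff_frac <= 1)
  structure(list(canopy_frac = canopy_frac, shrub_blackened = shrub_blackened,
                 surface_frac = surface_frac, rsc_woody_frac = rsc_woody_frac,
                 rsc_duff_frac = rsc_duff_frac),
            class = "consume_params")
}

#' Compute fuel consumption for a bed under a fire type
#'
#' A parameterized consumption scheme: canopy is consumed at a fixed fraction
#' (50% under wildfire conditions, 0% under prescribed burns), shrub at the
#' blackened fraction (50% both types), and the surface categories (nonwoody,
#' woody, duff) at a fraction that decreases linearly with fuel moisture.
#' Consumed woody fuel and duff are partly assigned to residual smoldering
#' combustion (RSC); everything else is short-term flaming and smoldering
#' (STFS).
#'
#' @param bed Data.frame with loading columns `canopy`, `shrub`, `nonwoody`,
#'   `woody`, `duff` (kg/km2). Vectorized over rows.
#' @param fuel_moisture Fuel moisture fraction in \[0, 1\], recycled over rows.
#' @param fire_type `"wildfire"` or `"rx"`.
#' @param params A [consume_params()].
#' @return Data.frame of class `consumption` with per-category consumed mass
#'   per area (kg/km2), the STFS/RSC split (`stfs_total`, `rsc_woody`,
#'   `rsc_duff`) and `total`.
#' @export
consume_fuels <- function(bed, fuel_moisture,
                          fire_type = c("wildfire", "rx"),
                          params = consume_params()) {
  fire_type <- match.arg(fire_type)
  bed <- as.data.frame(as.list(bed))
  if (any(fuel_moisture < 0 | fuel_moisture > 1))
    stop("fuel moisture must be in [0, 1]")
  sf <- params$surface_frac
  f_surf <- sf[1] + (sf[2] - sf[1]) * fuel_moisture
  canopy <- params$canopy_frac[[fire_type]] * bed$canopy
  shrub <- params$shrub_blackened * bed$shrub
  nonwoody <- f_surf * bed$nonwoody
  woody <- f_surf * bed$woody
  duff <- f_surf * bed$duff
  rsc_woody <- params$rsc_woody_frac * woody
  rsc_duff <- params$rsc_duff_frac * duff
  stfs_total <- canopy + shrub + nonwoody + (woody - rsc_woody) +
    (duff - rsc_duff)
  out <- data.frame(canopy = canopy, shrub = shrub, nonwoody = nonwoody,
                    woody = woody, duff = duff,
                    stfs_total = stfs_total, rsc_woody = rsc_woody,
                    rsc_duff = rsc_duff,
                    total = canopy + shrub + nonwoody + woody + duff)
  structure(out, class = c("consumption", "data.frame"))
}

#' Default PM2.5 emission-factor table
#'
#' Reads the shipped CSV of PM2.5 emission factors (g per kg of fuel
#' consumed) by land-cover type, fire type and combustion phase. Western
#' forest has distinct wildfire and prescribed-burn STFS factors; woody and
#' duff residual smoldering have their own factors regardless of cover.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `cover_type`, `fire_type`, `phase`, `species`, `ef_g_per_kg` (rows with
#'   `cover_type` or `fire_type` `"any"` act as wildcards).
#' @return A data.frame of class `ef_table`.
#' @export
default_ef_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "emission_factors_pm25.csv",
                        package = "rxsmoke", mustWork = TRUE)
  ef <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cover_type", "fire_type", "phase", "species", "ef_g_per_kg")
  if (!all(need %in% names(ef)))
    stop("EF table must have columns: ", paste(need, collapse = ", "))
  if (any(ef$ef_g_per_kg <= 0)) stop("all emission factors must be > 0")
  structure(ef, class = c("ef_table", "data.frame"))
}

# single-phase EF lookup with "any" wildcards; vectorized over cover/fire
ef_lookup <- function(ef_table, cover_type, fire_type, species, phase) {
  tab <- ef_table[ef_table$species == species & ef_table$phase == phase, ]
  n <- max(length(cover_type), length(fire_type))
  cover_type <- rep_len(cover_type, n)
  fire_type <- rep_len(fire_type, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hit <- tab[(tab$cover_type == cover_type[i] | tab$cover_type == "any") &
               (tab$fire_type == fire_type[i] | tab$fire_type == "any"), ]
    if (nrow(hit) == 0)
      stop(sprintf("no emission factor for %s/%s/%s/%s",
                   cover_type[i], fire_type[i], species, phase))
    # prefer the most specific entry
    specific <- (hit$cover_type != "any") + (hit$fire_type != "any")
    out[i] <- hit$ef_g_per_kg[which.max(specific)]
  }
  out
}

#' Species emissions from burned area and consumption
#'
#' Emitted mass is burned area times fuel consumed times the emission
#' factor, summed over combustion phases: STFS consumption uses the
#' cover-type (and, for forest, fire-type) STFS factor; residual smoldering
#' woody and duff use the RSC factors.
#'
#' @param burned_area_km2 Burned area, km2. Recycled over consumption rows.
#' @param consumption A [consume_fuels()] result (columns `stfs_total`,
#'   `rsc_woody`, `rsc_duff`, kg/km2).
#' @param cover_type Cover type(s): `"forest"`, `"shrubland"`, `"grassland"`.
#' @param fire_type `"wildfire"` or `"rx"`.
#' @param ef_table An [default_ef_table()]-style table.
#' @param species Species name present in the table. Default `"PM25"`.
#' @return Numeric vector of emitted mass in grams.
#' @export
compute_emissions <- function(burned_area_km2, consumption, cover_type,
                              fire_type = c("wildfire", "rx"),
                              ef_table = default_ef_table(),
                              species = "PM25") {
  fire_type <- match.arg(fire_type)
  if (any(burned_area_km2 < 0)) stop("burned area must be non-negative")
  ef_stfs <- ef_lookup(ef_table, cover_type, fire_type, species, "stfs")
  ef_w <- ef_lookup(ef_table, cover_type, fire_type, species, "rsc_woody")
  ef_d <- ef_lookup(ef_table, cover_type, fire_type, species, "rsc_duff")
  burned_area_km2 * (consumption$stfs_total * ef_stfs +
                     consumption$rsc_woody * ef_w +
                     consumption$rsc_duff * ef_d)
}

#' Build a fire emission inventory
#'
#' For every fire-day record: look up the cell's fuel bed, derive fuel
#' moisture from that day's soil moisture, compute consumption under the
#' scenario's fire type, and convert to emitted species mass.
#'
#' @param fires A `fire_events` data.frame (`day`, `row`, `col`, `area_km2`).
#' @param beds A [generate_fuelbeds()]-style `fuel_beds` table in cell order.
#' @param met A [generate_meteorology()] `fire_met` object.
#' @param fire_type `"wildfire"` or `"rx"`.
#' @param ef_table Emission-factor table.
#' @param species Species name. Default `"PM25"`.
#' @param cparams A [consume_params()].
#' @param fm_range Fuel-moisture range for [fuel_moisture_from_soil()].
#' @return A data.frame of class `emission_inventory`: one row per fire-day
#'   with `fire_id`, `event_id`, `day`, `row`, `col`, `area_km2`,
#'   `cover_type`, `fuel_moisture`, `consumption_kg` (total fuel consumed,
#'   kg), `species`, `mass_g`.
#' @export
build_inventory <- function(fires, beds, met,
                            fire_type = c("wildfire", "rx"),
                            ef_table = default_ef_table(), species = "PM25",
                            cparams = consume_params(),
                            fm_range = c(0.05, 0.40)) {
  fire_type <- match.arg(fire_type)
  grid <- met$grid
  n <- nrow(fires)
  if (n == 0) {
    out <- data.frame(fire_id = integer(), event_id = integer(),
                      day = integer(), row = integer(), col = integer(),
                      area_km2 = numeric(), cover_type = character(),
                      fuel_moisture = numeric(), consumption_kg = numeric(),
                      species = character(), mass_g = numeric())
    return(structure(out, class = c("emission_inventory", "data.frame")))
  }
  idx <- cell_index(grid, fires$row, fires$col)
  bed <- beds[idx, , drop = FALSE]
  soil <- met$soil[cbind(fires$day, fires$row, fires$col)]
  fm <- fuel_moisture_from_soil(soil, fm_range)
  cons <- consume_fuels(bed, fm, fire_type, cparams)
  mass <- compute_emissions(fires$area_km2, cons, bed$cover_type, fire_type,
                            ef_table, species)
  ev <- if ("event_id" %in% names(fires)) fires$event_id else seq_len(n)
  out <- data.frame(fire_id = seq_len(n), event_id = ev, day = fires$day,
                    row = fires$row, col = fires$col,
                    area_km2 = fires$area_km2, cover_type = bed$cover_type,
                    fuel_moisture = fm,
                    consumption_kg = cons$total * fires$area_km2,
                    species = species, mass_g = mass)
  structure(out, class = c("emission_inventory", "data.frame"))
}

# round half away from zero, matching the bracketed integer percings style
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize emission inventories across scenarios
#'
#' Computes per-scenario totals (burned area km2, fuel consumption Tg,
#' species mass Tg), percent reductions of each scenario against the
#' baseline, daily emission time series, and the number of days with
#' emissions above one tonne.
#'
#' @param inventories Named list of `emission_inventory` data.frames; names
#'   are scenario labels.
#' @param baseline Name of the baseline (wildfire) scenario.
#' @param species Species to summarize.
#' @return A list of class `inventory_summary` with elements `totals` (long
#'   data.frame `scenario`, `variable`, `value`), `reduction_pct` (integer
#'   percent reductions vs baseline, `NA` where the baseline total is zero),
#'   `daily` (day x scenario mass in g) and `days_over_1t`.
#' @export
summarize_inventory <- function(inventories, baseline = names(inventories)[1],
                                species = "PM25") {
  stopifnot(is.list(inventories), length(inventories) >= 1,
            baseline %in% names(inventories))
  scen <- names(inventories)
  tot <- lapply(inventories, function(inv) {
    inv <- inv[inv$species == species, , drop = FALSE]
    c(burned_area_km2 = sum(inv$area_km2),
      fuel_consumption_Tg = sum(inv$consumption_kg) / 1e9,
      species_Tg = sum(inv$mass_g) / 1e12)
  })
  totals <- do.call(rbind, lapply(scen, function(s) {
    data.frame(scenario = s, variable = names(tot[[s]]),
               value = unname(tot[[s]]))
  }))
  vars <- unique(totals$variable)
  red <- sapply(setdiff(scen, baseline), function(s) {
    sapply(vars, function(v) {
      b <- tot[[baseline]][[v]]
      if (b == 0) return(NA_real_)
      round_half_up(100 * (1 - tot[[s]][[v]] / b))
    })
  })
  red <- matrix(red, nrow = length(vars),
                dimnames = list(vars, setdiff(scen, baseline)))
  daily <- sapply(inventories, function(inv) {
    inv <- inv[inv$species == species, , drop = FALSE]
    d <- numeric(365)
    if (nrow(inv)) {
      agg <- tapply(inv$mass_g, inv$day, sum)
      d[as.integer(names(agg))] <- agg
    }
    d
  })
  daily <- matrix(daily, nrow = 365, dimnames = list(NULL, scen))
  days_over_1t <- colSums(daily > 1e6) # 1 tonne = 1e6 g
  structure(list(totals = totals, reduction_pct = red, daily = daily,
                 days_over_1t = days_over_1t, baseline = baseline,
                 species = species),
            class = "inventory_summary")
}

#' @export
print.inventory_summary <- function(x, ...) {
  cat("inventory_summary (", x$species, ", baseline ", x$baseline, ")\n",
      sep = "")
  wide <- stats::reshape(x$totals, idvar = "variable", timevar = "scenario",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  cat("days with emissions > 1 tonne:\n")
  print(x$days_over_1t)
  invisible(x)
}
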