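# Plain-text readers and writers for the pipeline's tables and gridded
# fields. Gridded daily fields travel as long-format CSV (day,row,col,value);
# tables as ordinary CSV; run configuration as YAML; summaries as JSON.

#' Write / read fire events as CSV
#'
#' Columns: `event_id`, `day`, `date` (label), `row`, `col`, `area_km2`.
#' @param fires A `fire_events` data.frame.
#' @param path File path.
#' @return `read_fire_events()` returns a `fire_events` data.frame.
#' @export
write_fire_events <- function(fires, path) {
  out <- as.data.frame(fires)
  out$date <- doy_label(out$day)
  write.csv(out[, c("event_id", "day", "date", "row", "col", "area_km2")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fire_events
#' @export
read_fire_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[, c("event_id", "day", "row", "col", "area_km2")]
  structure(df, class = c("fire_events", "data.frame"))
}

#' Write / read a gridded daily field as long-format CSV
#'
#' @param field Array `[365, n_rows, n_cols]`.
#' @param path File path.
#' @param var Column name for the value.
#' @param drop_zero Omit zero cells (keeps sparse fields small).
#' @param grid A [domain_grid()] (needed to rebuild the array).
#' @return `read_field_csv()` returns the array.
#' @export
write_field_csv <- function(field, path, var = "value", drop_zero = TRUE) {
  d <- dim(field)
  idx <- which(if (drop_zero) field != 0 else TRUE, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  df <- data.frame(day = idx[, 1], row = idx[, 2], col = idx[, 3],
                   value = field[idx])
  names(df)[4] <- var
  df <- df[order(df$day, df$row, df$col), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, grid, var = "value") {
  df <- read.csv(path)
  arr <- array(0, dim = c(365, grid$n_rows, grid$n_cols))
  arr[cbind(df$day, df$row, df$col)] <- df[[var]]
  arr
}

#' Write a population matrix as CSV
#' @param pop Population matrix.
#' @param path File path.
#' @export
write_population_csv <- function(pop, path) {
  idx <- which(pop >= 0, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2], population = pop[idx])
  df <- df[order(df$row, df$col), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a schedule result as CSV
#'
#' Columns: `fire_id`, `event_id`, `orig_date`, `new_date`, `tier`,
#' `collapsed` plus day-of-year and cell columns.
#' @param result A [build_scenario()] `schedule_result`.
#' @param path File path.
#' @export
write_schedule_csv <- function(result, path) {
  s <- result$schedule
  s$orig_date <- doy_label(s$orig_day)
  s$new_date <- doy_label(s$day)
  write.csv(s[, c("fire_id", "event_id", "row", "col", "area_km2",
                  "orig_day", "orig_date", "day", "new_date", "tier",
                  "collapsed")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The YAML file may contain any of the [run_config()] blocks (`seed`,
#' `grid`, `synth`, `criteria`, `screening`, `surrogate`, `health`,
#' `evaluation`, `species`); missing entries keep their defaults.
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1L
  y$seed <- NULL
  do.call(run_config, c(list(seed = seed), y))
}

#' Write per-scenario annual summaries as JSON
#'
#' @param run A [run_pipeline()] `fire_run`.
#' @param path File path.
#' @export
write_summary_json <- function(run, path) {
  out <- list(
    seed = run$config$seed,
    totals = run$summary$totals,
    reduction_pct = as.data.frame(run$summary$reduction_pct),
    days_over_1t = as.list(run$summary$days_over_1t),
    deaths = lapply(run$health, function(h)
      as.list(h$annual$annual_deaths)),
    fallback_area_frac = lapply(run$schedules, `[[`, "fallback_area_frac")
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
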