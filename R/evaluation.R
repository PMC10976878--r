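#' Match monitoring stations to nearest grid cells
#'
#' Each station is assigned the grid cell whose centre is Euclidean-nearest.
#' Distance ties break to the lower row index, then the lower column index.
#' Stations outside the grid extent are dropped with a warning.
#'
#' @param stations Data.frame with `station_id`, `x`, `y` (km, same frame as
#'   the grid).
#' @param grid A [domain_grid()].
#' @return The stations data.frame with added `row`, `col`.
#' @export
match_stations <- function(stations, grid) {
  stopifnot(all(c("station_id", "x", "y") %in% names(stations)))
  xmin <- grid$origin[1]; ymin <- grid$origin[2]
  xmax <- xmin + grid$n_cols * grid$cell_size
  ymax <- ymin + grid$n_rows * grid$cell_size
  inside <- stations$x >= xmin & stations$x <= xmax &
    stations$y >= ymin & stations$y <= ymax
  if (any(!inside)) {
    warning(sum(!inside), " station(s) outside the grid extent excluded: ",
            paste(stations$station_id[!inside], collapse = ", "))
    stations <- stations[inside, , drop = FALSE]
  }
  cc <- cell_centers(grid) # column-major, row fastest => lower row, then col,
  # wins ties via which.min's first-minimum rule
  stations$row <- NA_integer_; stations$col <- NA_integer_
  for (i in seq_len(nrow(stations))) {
    d2 <- (cc$x - stations$x[i])^2 + (cc$y - stations$y[i])^2
    j <- which.min(d2)
    stations$row[i] <- cc$row[j]; stations$col[i] <- cc$col[j]
  }
  rownames(stations) <- NULL
  stations
}

#' Normalized mean bias factor
#'
#' A symmetric bias metric: `mean(M)/mean(O) - 1` when the model mean is at
#' least the observed mean, and `1 - mean(O)/mean(M)` otherwise, so that
#' over- and under-prediction by the same factor give values of equal
#' magnitude and opposite sign.
#'
#' @param modeled,observed Paired numeric series; NA pairs dropped.
#' @return The NMBF (dimensionless).
#' @export
nmbf <- function(modeled, observed) {
  p <- .paired(modeled, observed)
  mm <- mean(p$m); mo <- mean(p$o)
  if (mm <= 0 || mo <= 0) stop("NMBF requires positive means")
  if (mm >= mo) mm / mo - 1 else 1 - mo / mm
}

#' Normalized mean absolute error factor
#'
#' `sum(|M_i - O_i|)` normalized by `n * mean(O)` when the model mean is at
#' least the observed mean, else by `n * mean(M)` (the same branch rule as
#' [nmbf()]), so NMAEF >= |NMBF| always.
#'
#' @inheritParams nmbf
#' @return The NMAEF (dimensionless, >= 0).
#' @export
nmaef <- function(modeled, observed) {
  p <- .paired(modeled, observed)
  mm <- mean(p$m); mo <- mean(p$o)
  if (mm <= 0 || mo <= 0) stop("NMAEF requires positive means")
  denom <- if (mm >= mo) length(p$o) * mo else length(p$m) * mm
  sum(abs(p$m - p$o)) / denom
}

.paired <- function(modeled, observed) {
  stopifnot(length(modeled) == length(observed))
  ok <- !is.na(modeled) & !is.na(observed)
  if (!any(ok)) stop("no complete modeled/observed pairs")
  list(m = modeled[ok], o = observed[ok])
}

# Pearson r with pairwise NA handling; NA for degenerate (constant) series
.pearson <- function(modeled, observed) {
  p <- .paired(modeled, observed)
  if (stats::sd(p$m) == 0 || stats::sd(p$o) == 0) return(NA_real_)
  cor(p$m, p$o)
}

#' Evaluate a modeled concentration field against station observations
#'
#' Matches stations to nearest grid cells, pairs each station's daily
#' observations with the modeled series of its cell, and computes Pearson r,
#' NMBF and NMAEF per station plus equal-weight station averages.
#'
#' @param conc Modeled daily array `[365, n_rows, n_cols]`, ug/m3.
#' @param obs Data.frame with `station_id`, `x`, `y`, `day`, `pm25`.
#' @param grid A [domain_grid()].
#' @param months Optional integer months (1-12) restricting the comparison,
#'   e.g. `6:8` for summer.
#' @return A list of class `eval_stats`: `stations` (per-station data.frame
#'   with `r`, `nmbf`, `nmaef`, `n`) and `average` (equal-weight means,
#'   NA-dropped for r).
#' @export
evaluate_stations <- function(conc, obs, grid, months = NULL) {
  stopifnot(all(c("station_id", "x", "y", "day", "pm25") %in% names(obs)))
  if (!is.null(months)) {
    if (length(months) == 0) stop("months subset must be non-empty")
    obs <- obs[doy_month(obs$day) %in% months, , drop = FALSE]
    if (nrow(obs) == 0) stop("no observations in the requested months")
  }
  st <- unique(obs[, c("station_id", "x", "y")])
  st <- match_stations(st, grid)
  rows <- lapply(seq_len(nrow(st)), function(i) {
    oi <- obs[obs$station_id == st$station_id[i], , drop = FALSE]
    m <- conc[cbind(oi$day, st$row[i], st$col[i])]
    data.frame(station_id = st$station_id[i], row = st$row[i],
               col = st$col[i], n = nrow(oi),
               r = .pearson(m, oi$pm25),
               nmbf = nmbf(m, oi$pm25),
               nmaef = nmaef(m, oi$pm25))
  })
  stations <- do.call(rbind, rows)
  avg <- c(r = mean(stations$r, na.rm = TRUE),
           nmbf = mean(stations$nmbf),
           nmaef = mean(stations$nmaef))
  structure(list(stations = stations, average = avg, months = months),
            class = "eval_stats")
}

#' Restrict an evaluation to a subset of months
#'
#' Convenience wrapper around [evaluate_stations()] with a month filter,
#' e.g. summer (June-August) when fire influence is strongest.
#'
#' @inheritParams evaluate_stations
#' @export
seasonal_subset <- function(conc, obs, grid, months) {
  evaluate_stations(conc, obs, grid, months = months)
}

#' @export
print.eval_stats <- function(x, ...) {
  lab <- if (is.null(x$months)) "all months" else
    paste("months", paste(x$months, collapse = ","))
  cat(sprintf(
    "eval_stats (%s, %d stations): mean r = %.2f, NMBF = %.2f, NMAEF = %.2f\n",
    lab, nrow(x$stations), x$average["r"], x$average["nmbf"],
    x$average["nmaef"]))
  invisible(x)
}
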