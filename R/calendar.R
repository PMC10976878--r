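# Non-leap 365-day calendar. All dates in the package are day-of-year
# integers 1..365; the study year is a label only.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_START <- c(0L, cumsum(.MONTH_DAYS))[1:12] # days before month m
.MONTH_OF_DOY <- rep(1:12, .MONTH_DAYS)
.MONTH_ABB <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Month of a day-of-year (non-leap calendar)
#' @param doy Integer day-of-year, 1-365.
#' @return Integer month 1-12.
#' @export
doy_month <- function(doy) {
  stopifnot(all(doy >= 1 & doy <= 365))
  .MONTH_OF_DOY[doy]
}

#' Season of a day-of-year
#'
#' Meteorological seasons: spring Mar-May, summer Jun-Aug, fall Sep-Nov,
#' winter Dec-Feb.
#' @param doy Integer day-of-year, 1-365.
#' @return Character vector in `c("winter","spring","summer","fall")`.
#' @export
doy_season <- function(doy) {
  m <- doy_month(doy)
  c("winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer", "fall", "fall", "fall", "winter")[m]
}

#' Convert month/day to day-of-year (non-leap calendar)
#' @param month Integer month 1-12.
#' @param day Integer day of month.
#' @return Integer day-of-year.
#' @export
mdy_doy <- function(month, day) {
  stopifnot(all(month >= 1 & month <= 12), all(day >= 1),
            all(day <= .MONTH_DAYS[month]))
  .MONTH_START[month] + as.integer(day)
}

#' Human-readable label for a day-of-year
#' @param doy Integer day-of-year.
#' @return Character like `"Mar 01"`.
#' @export
doy_label <- function(doy) {
  m <- doy_month(doy)
  sprintf("%s %02d", .MONTH_ABB[m], doy - .MONTH_START[m])
}

#' Days in the prescribed-burn seasons
#'
#' Spring (March through May) and fall (September through November), the
#' windows in which prescribed burning is considered feasible.
#' @return Integer vector of day-of-year values.
#' @export
burn_season_days <- function() {
  c(mdy_doy(3, 1):mdy_doy(5, 31), mdy_doy(9, 1):mdy_doy(11, 30))
}
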