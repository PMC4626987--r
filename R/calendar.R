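# 365-day (no-leap) calendar used throughout the package.  Climate-model
# output is commonly archived on this calendar and it keeps annual day
# counts constant, so every year contributes exactly 365 classified days.

#' Days per month on the 365-day calendar
#' @keywords internal
.MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' @keywords internal
.DAYS_PER_YEAR <- 365L

# month index (1..12) for each day-of-year 1..365
.DOY_MONTH <- rep.int(seq_len(12L), .MONTH_LENGTHS)

#' Month of each day of year (365-day calendar)
#'
#' @param doy Integer day-of-year in 1..365.
#' @return Integer month in 1..12.
#' @examples
#' monthOfDay(c(1, 31, 32, 365))
#' @export
monthOfDay <- function(doy) {
  doy <- as.integer(doy)
  if (any(doy < 1L | doy > .DAYS_PER_YEAR))
    stop("day-of-year must lie in 1..365 (no-leap calendar)")
  .DOY_MONTH[doy]
}

#' Days in a calendar month (365-day calendar)
#'
#' @param month Integer month in 1..12.
#' @return Integer number of days.
#' @export
daysInMonth <- function(month) {
  month <- as.integer(month)
  if (any(month < 1L | month > 12L)) stop("month must lie in 1..12")
  .MONTH_LENGTHS[month]
}

# expand an inclusive year range into the per-day (year, doy, month) axis
.timeAxis <- function(years) {
  yrs <- seq.int(years[1], years[2])
  list(
    year  = rep(yrs, each = .DAYS_PER_YEAR),
    doy   = rep.int(seq_len(.DAYS_PER_YEAR), length(yrs)),
    month = rep.int(.DOY_MONTH, length(yrs)),
    years = yrs
  )
}

# validate an inclusive year range c(first, last)
.checkYearRange <- function(x, what = "year range") {
  if (length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop(what, " must be an inclusive c(first, last) with first <= last")
  as.integer(x)
}
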