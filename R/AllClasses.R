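#' @import methods
NULL

# ---------------------------------------------------------------------------
# Gridded containers.  All grids are regular lat-lon: latitudes ascending
# south -> north, longitudes ascending in [-180, 180).  Daily data live on
# the 365-day no-leap calendar, ordered year-major then day-of-year.
# ---------------------------------------------------------------------------

#' GriddedDailyField: one daily variable on a (time, lat, lon) grid
#'
#' The atomic input of the pipeline: a single variable (`tmax`, `rh`,
#' `wind` or `atmax`) on a regular latitude-longitude grid with a daily
#' time axis on the 365-day calendar, covering an inclusive range of
#' whole years.
#'
#' @slot values numeric array `[time, lat, lon]`; `time` runs year-major,
#'   day-of-year minor, `365 * nYears` steps.
#' @slot variable single variable name.
#' @slot units unit string (degC, percent, m/s).
#' @slot years inclusive year range `c(first, last)`.
#' @slot lat,lon ascending cell-centre coordinates in degrees.
#' @export
setClass("GriddedDailyField",
  representation(
    values   = "array",
    variable = "character",
    units    = "character",
    years    = "integer",
    lat      = "numeric",
    lon      = "numeric"
  )
)

setValidity("GriddedDailyField", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-d [time, lat, lon] array")
  yrs <- object@years
  if (length(yrs) != 2L || yrs[1] > yrs[2])
    msg <- c(msg, "years must be an inclusive c(first, last)")
  else {
    nT <- (yrs[2] - yrs[1] + 1L) * .DAYS_PER_YEAR
    if (length(d) == 3L && d[1] != nT)
      msg <- c(msg, sprintf("time dimension is %d but years imply %d", d[1], nT))
  }
  if (length(d) == 3L && d[2] != length(object@lat))
    msg <- c(msg, "lat dimension mismatch")
  if (length(d) == 3L && d[3] != length(object@lon))
    msg <- c(msg, "lon dimension mismatch")
  if (is.unsorted(object@lat, strictly = TRUE))
    msg <- c(msg, "lat must be strictly ascending")
  if (is.unsorted(object@lon, strictly = TRUE))
    msg <- c(msg, "lon must be strictly ascending")
  if (length(object@variable) != 1L) msg <- c(msg, "variable must be length 1")
  if (length(msg)) msg else TRUE
})

#' ClimatologyGrid: 12 monthly mean layers for one variable
#'
#' Long-term mean per calendar month over a baseline averaging window
#' (default 1961-1990).  Serves both as a model climatology and as the
#' observed reference that bias correction matches.
#'
#' @slot values numeric array `[12, lat, lon]`.
#' @slot variable variable name.
#' @slot baseline inclusive year range the means were taken over.
#' @slot lat,lon cell-centre coordinates.
#' @export
setClass("ClimatologyGrid",
  representation(
    values   = "array",
    variable = "character",
    baseline = "integer",
    lat      = "numeric",
    lon      = "numeric"
  )
)

setValidity("ClimatologyGrid", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != 12L)
    msg <- c(msg, "values must be a [12, lat, lon] array (exactly 12 monthly layers)")
  if (length(d) == 3L && (d[2] != length(object@lat) || d[3] != length(object@lon)))
    msg <- c(msg, "lat/lon dimension mismatch")
  if (length(object@baseline) != 2L || object@baseline[1] > object@baseline[2])
    msg <- c(msg, "baseline must be an inclusive c(first, last)")
  if (length(msg)) msg else TRUE
})

#' CorrectionField: monthly bias-correction layers
#'
#' Twelve per-cell correction layers for one variable, either additive
#' offsets (degC) or multiplicative factors (dimensionless).  Cells where a
#' multiplicative factor could not be formed (zero model climatology) are NA.
#'
#' @slot values numeric array `[12, lat, lon]`.
#' @slot variable variable name the correction applies to.
#' @slot mode `"additive"` or `"multiplicative"`.
#' @slot lat,lon cell-centre coordinates.
#' @export
setClass("CorrectionField",
  representation(
    values   = "array",
    variable = "character",
    mode     = "character",
    lat      = "numeric",
    lon      = "numeric"
  )
)

setValidity("CorrectionField", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != 12L)
    msg <- c(msg, "values must be a [12, lat, lon] array")
  if (!object@mode %in% c("additive", "multiplicative"))
    msg <- c(msg, "mode must be 'additive' or 'multiplicative'")
  if (object@mode == "multiplicative") {
    v <- object@values
    if (any(is.finite(v) & v <= 0))
      msg <- c(msg, "multiplicative factors must be finite and > 0 where defined")
  }
  if (length(msg)) msg else TRUE
})

#' ClimateEnsemble: member-labelled bundles of daily fields
#'
#' A collection of ensemble members, each carrying the three daily fields
#' the pipeline consumes: `tmax`, `rh` and `wind` on a shared grid and
#' time axis.
#'
#' @slot members named list; each element is a list with components
#'   `tmax`, `rh`, `wind`, all [GriddedDailyField]s on identical axes.
#' @export
setClass("ClimateEnsemble", representation(members = "list"))

setValidity("ClimateEnsemble", function(object) {
  msg <- character()
  if (length(object@members) < 1L) msg <- c(msg, "at least one member required")
  if (is.null(names(object@members)) || anyDuplicated(names(object@members)))
    msg <- c(msg, "members must be uniquely named")
  for (m in object@members) {
    if (!is.list(m) || !all(c("tmax", "rh", "wind") %in% names(m))) {
      msg <- c(msg, "each member needs tmax, rh and wind fields")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' AnnualCountGrid: per-year, per-cell day counts for one category
#'
#' Integer counts of days per calendar year falling in one hot-day
#' category (Hda1-Hda5) or symptom band (I-IV), per grid cell.
#'
#' @slot counts integer array `[year, lat, lon]`.
#' @slot category category label, e.g. `"Hda2"` or `"BandII"`.
#' @slot years inclusive year range.
#' @slot lat,lon cell-centre coordinates.
#' @export
setClass("AnnualCountGrid",
  representation(
    counts   = "array",
    category = "character",
    years    = "integer",
    lat      = "numeric",
    lon      = "numeric"
  )
)

setValidity("AnnualCountGrid", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) msg <- c(msg, "counts must be a [year, lat, lon] array")
  yrs <- object@years
  if (length(yrs) != 2L || yrs[1] > yrs[2])
    msg <- c(msg, "years must be an inclusive c(first, last)")
  else if (length(d) == 3L && d[1] != yrs[2] - yrs[1] + 1L)
    msg <- c(msg, "year dimension does not match year range")
  cnt <- object@counts
  ok <- is.na(cnt) | (cnt >= 0 & cnt <= .DAYS_PER_YEAR)
  if (!all(ok)) msg <- c(msg, "counts must lie in [0, 365]")
  if (length(msg)) msg else TRUE
})

#' TimeSliceSummary: per-cell mean days/year over a 30-year slice
#'
#' @slot values numeric matrix `[lat, lon]` of mean days per year.
#' @slot slice inclusive year range of the averaging window.
#' @slot category count category summarised.
#' @slot lat,lon cell-centre coordinates.
#' @export
setClass("TimeSliceSummary",
  representation(
    values   = "matrix",
    slice    = "integer",
    category = "character",
    lat      = "numeric",
    lon      = "numeric"
  )
)

setValidity("TimeSliceSummary", function(object) {
  v <- object@values
  ok <- is.na(v) | (v >= 0 & v <= .DAYS_PER_YEAR)
  if (!all(ok)) return("mean days/year must lie in [0, 365]")
  TRUE
})

#' TrendTest: Monte Carlo trend test result for one series
#'
#' @slot slope observed ordinary-least-squares slope (days/year per year of
#'   the series' time axis).
#' @slot rate average rate of increase of the smoothed series (days/year).
#' @slot exceedFraction fraction of null-resample slopes strictly below the
#'   observed slope (ties count against significance).
#' @slot significant named logical at the tested confidence levels.
#' @slot levels confidence levels tested (percent).
#' @slot nIter number of Monte Carlo resamples.
#' @slot seed RNG seed used.
#' @slot alternative `"greater"` (one-sided increasing) or `"two.sided"`.
#' @export
setClass("TrendTest",
  representation(
    slope          = "numeric",
    rate           = "numeric",
    exceedFraction = "numeric",
    significant    = "logical",
    levels         = "numeric",
    nIter          = "integer",
    seed           = "integer",
    alternative    = "character"
  )
)

setValidity("TrendTest", function(object) {
  msg <- character()
  if (length(object@levels) && length(object@significant) != length(object@levels))
    msg <- c(msg, "one significance flag per level required")
  # significance at a stricter level implies it at every looser level
  if (length(object@levels) > 1L) {
    o <- order(object@levels)
    s <- object@significant[o]
    if (any(diff(as.integer(s)) > 0L))
      msg <- c(msg, "significance at a high level must imply it at lower levels")
  }
  if (length(msg)) msg else TRUE
})

#' TrendGrid: per-cell rates and Monte Carlo significance flags
#'
#' @slot rate numeric matrix `[lat, lon]`, average rate in days/year.
#' @slot flag integer matrix `[lat, lon]`: 0 = not significant, 90/95/99 =
#'   highest confidence level attained, -1 = no trend possible (series
#'   structurally constant at 0 or 365 days).
#' @slot category count category tested.
#' @slot nIter,seed Monte Carlo settings.
#' @slot lat,lon cell-centre coordinates.
#' @export
setClass("TrendGrid",
  representation(
    rate     = "matrix",
    flag     = "matrix",
    category = "character",
    nIter    = "integer",
    seed     = "integer",
    lat      = "numeric",
    lon      = "numeric"
  )
)

setValidity("TrendGrid", function(object) {
  f <- object@flag
  if (!all(f %in% c(-1L, 0L, 90L, 95L, 99L)))
    return("flags must be in {-1, 0, 90, 95, 99}")
  if (!identical(dim(object@rate), dim(object@flag)))
    return("rate and flag dimensions differ")
  TRUE
})
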