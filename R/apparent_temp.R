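# Apparent temperature (AT): the non-radiative Australian Bureau of
# Meteorology heat index,
#
#   AT = Ta + 0.33 * e - 0.70 * ws - 4.00
#
# with Ta the dry-bulb temperature (degC), e the water vapour pressure
# (hPa) and ws the 10 m wind speed (m/s).  Vapour pressure is derived from
# relative humidity through the Magnus saturation curve published alongside
# the index.  By convention the daily maximum AT is formed from the same
# day's tmax, RH and wind, with e evaluated at tmax.

# Magnus constants, fixed in one place
.MAGNUS_A <- 6.105   # hPa
.MAGNUS_B <- 17.27
.MAGNUS_C <- 237.7   # degC

#' Saturation vapour pressure (Magnus form)
#'
#' `e_s(Ta) = 6.105 * exp(17.27 * Ta / (237.7 + Ta))` hPa; strictly
#' increasing in `Ta`.
#'
#' @param ta dry-bulb temperature, degC, in (-60, 60).
#' @return Saturation vapour pressure in hPa.
#' @examples
#' saturationVaporPressure(0)   # 6.105
#' @export
saturationVaporPressure <- function(ta) {
  if (any(!is.na(ta) & (ta <= -60 | ta >= 60)))
    stop("temperature outside the physically plausible range (-60, 60) degC")
  .MAGNUS_A * exp(.MAGNUS_B * ta / (.MAGNUS_C + ta))
}

#' Water vapour pressure from relative humidity
#'
#' `e = (rh / 100) * e_s(Ta)`.
#'
#' @param ta dry-bulb temperature, degC.
#' @param rh relative humidity, percent, in [0, 100].
#' @return Vapour pressure in hPa.
#' @examples
#' vaporPressure(0, 50)  # 3.0525
#' @export
vaporPressure <- function(ta, rh) {
  if (any(!is.na(rh) & (rh < 0 | rh > 100)))
    stop("relative humidity must lie in [0, 100]")
  (rh / 100) * saturationVaporPressure(ta)
}

#' Apparent temperature
#'
#' `AT = Ta + 0.33 * e - 0.70 * ws - 4.00` (degC).  Negative results are
#' retained; they only ever fall below the lowest health threshold.
#'
#' @param ta dry-bulb temperature, degC.
#' @param e water vapour pressure, hPa.
#' @param ws wind speed at 10 m, m/s, >= 0.
#' @return Apparent temperature in degC.
#' @examples
#' apparentTemperature(30, 20, 5)  # 29.1
#' @export
apparentTemperature <- function(ta, e, ws) {
  if (any(!is.na(ws) & ws < 0)) stop("wind speed must be >= 0")
  ta + 0.33 * e - 0.70 * ws - 4.00
}

#' Daily maximum apparent temperature field
#'
#' Element-wise AT over three aligned daily fields:
#' `ATmax = AT(tmax, e(tmax, rh), wind)`.  Any missing input yields a
#' missing output cell.
#'
#' @param tmax,rh,wind [GriddedDailyField]s on identical grids and time
#'   axes (variables `tmax`, `rh`, `wind`).
#' @return A [GriddedDailyField] with variable `atmax`, units degC.
#' @examples
#' ens <- generateEnsemble(synthConfig(nMembers = 1, years = c(1961, 1961),
#'                                     nLat = 2, nLon = 2))
#' m <- getMember(ens, "member1")
#' dailyATMax(m$tmax, m$rh, m$wind)
#' @export
dailyATMax <- function(tmax, rh, wind) {
  stopifnot(is(tmax, "GriddedDailyField"), is(rh, "GriddedDailyField"),
            is(wind, "GriddedDailyField"))
  sameAxes <- function(a, b) {
    identical(dim(a@values), dim(b@values)) &&
      isTRUE(all.equal(a@lat, b@lat)) && isTRUE(all.equal(a@lon, b@lon)) &&
      identical(a@years, b@years)
  }
  if (!sameAxes(tmax, rh) || !sameAxes(tmax, wind))
    stop("tmax, rh and wind must share grid and time axes")
  at <- apparentTemperature(tmax@values,
                            vaporPressure(tmax@values, rh@values),
                            wind@values)
  new("GriddedDailyField", values = at, variable = "atmax", units = "degC",
      years = tmax@years, lat = tmax@lat, lon = tmax@lon)
}
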