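# fixtures built in code: small configs and hand-made gridded fields

# a clean (bias-free, noise-free) config for closed-form checks
cleanConfig <- function(years = c(1961, 1970), nLat = 2, nLon = 2,
                        trend = 0, ...) {
  synthConfig(nMembers = 1, years = years, nLat = nLat, nLon = nLon,
              trendDegCPerCentury = trend,
              biasT = 0, biasRh = 1,
              noiseSdT = 0, noiseSdRh = 0, windSd = 0, ...)
}

# wrap a raw array (or scalar) into a GriddedDailyField
makeField <- function(values, years = c(1961, 1961), nLat = 2, nLon = 2,
                      variable = "tmax", units = "degC",
                      lat = seq(-30, by = 2, length.out = nLat),
                      lon = seq(18, by = 2, length.out = nLon)) {
  nT <- (years[2] - years[1] + 1L) * 365L
  if (length(values) == 1L) values <- array(values, c(nT, nLat, nLon))
  new("GriddedDailyField", values = values, variable = variable,
      units = units, years = as.integer(years), lat = lat, lon = lon)
}

makeClim <- function(values, nLat = 2, nLon = 2, variable = "tmax",
                     baseline = c(1961L, 1990L),
                     lat = seq(-30, by = 2, length.out = nLat),
                     lon = seq(18, by = 2, length.out = nLon)) {
  if (length(values) == 1L) values <- array(values, c(12L, nLat, nLon))
  new("ClimatologyGrid", values = values, variable = variable,
      baseline = as.integer(baseline), lat = lat, lon = lon)
}

# scalar-loop reference for annual hot-day / band counting
countOracle <- function(atmaxYear) {
  stopifnot(length(atmaxYear) == 365L)
  c(Hda1 = sum(atmaxYear < 27), Hda2 = sum(atmaxYear >= 27),
    Hda3 = sum(atmaxYear >= 32), Hda4 = sum(atmaxYear >= 39),
    Hda5 = sum(atmaxYear >= 51),
    BandI = sum(atmaxYear >= 27 & atmaxYear < 32),
    BandII = sum(atmaxYear >= 32 & atmaxYear < 39),
    BandIII = sum(atmaxYear >= 39 & atmaxYear < 51),
    BandIV = sum(atmaxYear >= 51))
}
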