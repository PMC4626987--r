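# Synthetic climate-ensemble generator.
#
# Emulates the statistical surface of a downscaled regional-model ensemble:
# six members by default over 1961-2100, hemisphere-aware seasonal cycles,
# a spatially varying linear warming trend, spatially varying humidity,
# systematic per-calendar-month model biases (additive in temperature,
# multiplicative in relative humidity) and day-to-day Gaussian noise with an
# optional AR(1) component.  The generator carries its own ground truth, so
# bias correction and trend estimation can be checked against closed forms.

#' SynthConfig: parameters of the synthetic climate generator
#'
#' @slot nMembers number of ensemble members.
#' @slot years inclusive simulated year range.
#' @slot lat,lon cell-centre coordinates (regular grid).
#' @slot tBase baseline annual-mean daily maximum temperature per latitude
#'   row (degC), length `nLat`.
#' @slot tSeasonalAmp amplitude of the seasonal cycle of tmax (degC).
#' @slot trendDegCPerCentury warming-rate field `[lat, lon]` (degC/100yr).
#' @slot rhBase baseline relative humidity field `[lat, lon]` (percent).
#' @slot rhTrendPerCentury humidity trend (percentage points/100yr).
#' @slot windMean,windSd mean and day-to-day s.d. of 10 m wind (m/s);
#'   wind carries no bias and no trend.
#' @slot biasT additive model bias in tmax per calendar month (degC, 12).
#' @slot biasRh multiplicative model bias factor in RH per month (12).
#' @slot noiseSdT,noiseSdRh day-to-day noise s.d. for tmax (degC) and RH
#'   (percentage points).
#' @slot ar1 lag-1 autocorrelation of the daily noise (0 = independent).
#' @slot seed RNG seed; the whole ensemble is reproducible given the seed.
#' @export
setClass("SynthConfig",
  representation(
    nMembers            = "integer",
    years               = "integer",
    lat                 = "numeric",
    lon                 = "numeric",
    tBase               = "numeric",
    tSeasonalAmp        = "numeric",
    trendDegCPerCentury = "matrix",
    rhBase              = "matrix",
    rhTrendPerCentury   = "numeric",
    windMean            = "numeric",
    windSd              = "numeric",
    biasT               = "numeric",
    biasRh              = "numeric",
    noiseSdT            = "numeric",
    noiseSdRh           = "numeric",
    ar1                 = "numeric",
    seed                = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nMembers < 1L) msg <- c(msg, "nMembers must be >= 1")
  if (length(object@years) != 2L || object@years[1] > object@years[2])
    msg <- c(msg, "years must be an inclusive c(first, last)")
  if (length(object@lat) < 1L || length(object@lon) < 1L)
    msg <- c(msg, "grid must have at least one cell")
  if (is.unsorted(object@lat, strictly = TRUE) ||
      is.unsorted(object@lon, strictly = TRUE))
    msg <- c(msg, "lat and lon must be strictly ascending")
  if (length(object@tBase) != length(object@lat))
    msg <- c(msg, "tBase must have one value per latitude row")
  dd <- c(length(object@lat), length(object@lon))
  if (!identical(dim(object@trendDegCPerCentury), dd))
    msg <- c(msg, "trendDegCPerCentury must be a [lat, lon] matrix")
  if (!identical(dim(object@rhBase), dd))
    msg <- c(msg, "rhBase must be a [lat, lon] matrix")
  if (length(object@biasT) != 12L || length(object@biasRh) != 12L)
    msg <- c(msg, "biasT and biasRh need 12 monthly values")
  if (any(object@biasRh <= 0))
    msg <- c(msg, "biasRh factors must be > 0")
  if (object@noiseSdT < 0 || object@noiseSdRh < 0 || object@windSd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  if (object@ar1 < 0 || object@ar1 >= 1)
    msg <- c(msg, "ar1 must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-climate configuration
#'
#' Defaults describe the study conditions the pipeline targets: six
#' ensemble members over 1961-2100 on a coarse African-style grid
#' (southern-hemisphere window), a 3 degC/century warming trend, a 6 degC
#' seasonal cycle of daily maximum temperature, moderate systematic model
#' biases, and 1 degC / 5 percentage-point daily noise.
#'
#' `tBase` may be given as a single number, a vector per latitude row, or
#' left `NULL` for a latitude-dependent default (warmer toward the
#' equator).  `trendDegCPerCentury` and `rhBase` may be scalars (recycled
#' over the grid) or full `[lat, lon]` matrices.
#'
#' @param nMembers number of ensemble members (default 6).
#' @param years inclusive year range (default `c(1961, 2100)`).
#' @param nLat,nLon grid size; `cellSizeDeg` cell size in degrees;
#'   `lat0,lon0` south-west cell centre.
#' @param tBase baseline annual-mean tmax (degC); see Details.
#' @param tSeasonalAmp seasonal amplitude (degC).
#' @param trendDegCPerCentury warming rate (degC/100yr), scalar or matrix.
#' @param rhBase baseline relative humidity (percent), scalar or matrix.
#' @param rhTrendPerCentury humidity trend (points/100yr).
#' @param windMean,windSd wind mean and daily s.d. (m/s).
#' @param biasT additive monthly tmax bias (degC, length 12 or scalar).
#' @param biasRh multiplicative monthly RH bias (length 12 or scalar).
#' @param noiseSdT,noiseSdRh daily noise s.d.
#' @param ar1 AR(1) coefficient of the daily noise.
#' @param seed RNG seed.
#' @return A validated [SynthConfig].
#' @examples
#' cfg <- synthConfig(nMembers = 2, years = c(1961, 1990), nLat = 2, nLon = 2)
#' @export
synthConfig <- function(nMembers = 6L,
                        years = c(1961L, 2100L),
                        nLat = 4L, nLon = 4L,
                        cellSizeDeg = 2,
                        lat0 = -30, lon0 = 18,
                        tBase = NULL,
                        tSeasonalAmp = 6,
                        trendDegCPerCentury = 3,
                        rhBase = 60,
                        rhTrendPerCentury = 0,
                        windMean = 3, windSd = 0.8,
                        biasT = 1.5 * cospi(2 * (0:11) / 12),
                        biasRh = 1 + 0.10 * sinpi(2 * (0:11) / 12),
                        noiseSdT = 1, noiseSdRh = 5,
                        ar1 = 0,
                        seed = 1L) {
  lat <- lat0 + cellSizeDeg * (seq_len(nLat) - 1L)
  lon <- lon0 + cellSizeDeg * (seq_len(nLon) - 1L)
  if (is.null(tBase)) tBase <- 32 - 0.22 * abs(lat)
  if (length(tBase) == 1L) tBase <- rep(tBase, nLat)
  asGrid <- function(x) {
    if (is.matrix(x)) x else matrix(x, nLat, nLon)
  }
  if (length(biasT) == 1L) biasT <- rep(biasT, 12L)
  if (length(biasRh) == 1L) biasRh <- rep(biasRh, 12L)
  new("SynthConfig",
      nMembers = as.integer(nMembers),
      years = .checkYearRange(years),
      lat = as.numeric(lat), lon = as.numeric(lon),
      tBase = as.numeric(tBase),
      tSeasonalAmp = as.numeric(tSeasonalAmp),
      trendDegCPerCentury = asGrid(trendDegCPerCentury),
      rhBase = asGrid(rhBase),
      rhTrendPerCentury = as.numeric(rhTrendPerCentury),
      windMean = as.numeric(windMean), windSd = as.numeric(windSd),
      biasT = as.numeric(biasT), biasRh = as.numeric(biasRh),
      noiseSdT = as.numeric(noiseSdT), noiseSdRh = as.numeric(noiseSdRh),
      ar1 = as.numeric(ar1),
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d member(s), %d-%d, %d x %d grid, seed %d\n  trend %.2g..%.2g degC/century, noise sd T %.2g degC / RH %.2g pts\n",
    object@nMembers, object@years[1], object@years[2],
    length(object@lat), length(object@lon), object@seed,
    min(object@trendDegCPerCentury), max(object@trendDegCPerCentury),
    object@noiseSdT, object@noiseSdRh
  ))
})

# seasonal cycle of tmax: hemisphere-aware cosine peaking mid-January in the
# southern hemisphere (doy 15) and mid-July (doy 196) at/ north of the equator
.seasonalCycle <- function(doy, lat, amp) {
  peak <- ifelse(lat < 0, 15, 196)
  amp * cos(2 * pi * outer(doy, peak, "-") / .DAYS_PER_YEAR)
}

# daily noise [nT, nLat, nLon]; AR(1) along time when ar1 > 0, scaled to
# keep the stationary standard deviation at sd
.dailyNoise <- function(nT, nLat, nLon, sd, ar1) {
  if (sd == 0) return(array(0, c(nT, nLat, nLon)))
  eps <- array(stats::rnorm(nT * nLat * nLon, sd = sd), c(nT, nLat, nLon))
  if (ar1 > 0) {
    innov <- sqrt(1 - ar1^2)
    eps <- apply(eps, c(2, 3), function(e)
      as.numeric(stats::filter(e * innov, ar1, method = "recursive")))
    dim(eps) <- c(nT, nLat, nLon)
  }
  eps
}

# deterministic (noise- and bias-free) daily tmax for one configuration:
# baseline + seasonal cycle + annual-step warming trend
.detTmax <- function(config, axis) {
  nLat <- length(config@lat); nLon <- length(config@lon)
  nT <- length(axis$year)
  seas <- .seasonalCycle(axis$doy, config@lat, config@tSeasonalAmp) # [nT, nLat]
  elapsed <- (axis$year - config@years[1]) / 100
  out <- array(0, c(nT, nLat, nLon))
  base <- matrix(config@tBase, nT, nLat, byrow = TRUE) + seas
  for (i in seq_len(nLon)) {
    out[, , i] <- base + outer(elapsed, config@trendDegCPerCentury[, i])
  }
  out
}

# deterministic daily RH before model bias (clipped to [0, 100])
.detRh <- function(config, axis) {
  nLat <- length(config@lat); nLon <- length(config@lon)
  nT <- length(axis$year)
  elapsed <- (axis$year - config@years[1]) / 100
  out <- array(0, c(nT, nLat, nLon))
  for (i in seq_len(nLon)) {
    out[, , i] <- matrix(config@rhBase[, i], nT, nLat, byrow = TRUE) +
      config@rhTrendPerCentury * elapsed
  }
  pmin(pmax(out, 0), 100)
}

#' Generate a synthetic climate ensemble
#'
#' Simulates `nMembers` bundles of daily `tmax`, `rh` and `wind` fields.
#' Daily tmax is baseline + hemisphere-aware seasonal cycle + linear
#' warming (stepping annually, in degC/century) + additive monthly model
#' bias + noise; RH is baseline + trend + noise, multiplied by the monthly
#' model bias factor and clipped to [0, 100]; wind is unbiased, untrended
#' mean + noise, floored at 0.  Bit-identical output for a given seed.
#'
#' @param config a [SynthConfig].
#' @return A [ClimateEnsemble] with members `member1..memberN`.
#' @examples
#' ens <- generateEnsemble(synthConfig(nMembers = 1, years = c(1961, 1965),
#'                                     nLat = 2, nLon = 2))
#' ens
#' @export
generateEnsemble <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  axis <- .timeAxis(config@years)
  nT <- length(axis$year)
  nLat <- length(config@lat); nLon <- length(config@lon)
  detT <- .detTmax(config, axis)
  detR <- .detRh(config, axis)
  biasTDay <- config@biasT[axis$month]
  biasRhDay <- config@biasRh[axis$month]

  mkField <- function(values, variable, units) {
    new("GriddedDailyField", values = values, variable = variable,
        units = units, years = config@years,
        lat = config@lat, lon = config@lon)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config@seed)

  members <- vector("list", config@nMembers)
  for (m in seq_len(config@nMembers)) {
    tmax <- detT + biasTDay +
      .dailyNoise(nT, nLat, nLon, config@noiseSdT, config@ar1)
    rh <- (detR + .dailyNoise(nT, nLat, nLon, config@noiseSdRh, config@ar1)) *
      biasRhDay
    rh <- pmin(pmax(rh, 0), 100)
    wind <- pmax(config@windMean +
                   .dailyNoise(nT, nLat, nLon, config@windSd, config@ar1), 0)
    members[[m]] <- list(
      tmax = mkField(tmax, "tmax", "degC"),
      rh   = mkField(rh, "rh", "percent"),
      wind = mkField(wind, "wind", "m/s")
    )
  }
  names(members) <- paste0("member", seq_len(config@nMembers))
  new("ClimateEnsemble", members = members)
}

#' Generate the bias-free reference climatology implied by a configuration
#'
#' Returns the monthly climatology an unbiased observer would record over
#' the baseline window: the noise-free expectation of the generator
#' *without* the model bias terms.  This is the "truth" that bias
#' correction of the generated ensemble should restore.
#'
#' @param config a [SynthConfig].
#' @param baseline inclusive baseline year range (default 1961-1990,
#'   clipped to the configured years).
#' @return Named list with [ClimatologyGrid]s `tmax` and `rh`.
#' @examples
#' ref <- generateReferenceClimatology(
#'   synthConfig(nMembers = 1, years = c(1961, 1990), nLat = 2, nLon = 2))
#' ref$tmax
#' @export
generateReferenceClimatology <- function(config, baseline = c(1961L, 1990L)) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  baseline <- .checkYearRange(baseline, "baseline")
  if (baseline[1] < config@years[1] || baseline[2] > config@years[2])
    stop("baseline must lie within the configured years")
  nLat <- length(config@lat); nLon <- length(config@lon)
  baseYears <- seq.int(baseline[1], baseline[2])
  meanElapsed <- mean(baseYears - config@years[1]) / 100

  # monthly mean of the seasonal cycle per latitude row
  seasAll <- .seasonalCycle(seq_len(.DAYS_PER_YEAR), config@lat,
                            config@tSeasonalAmp) # [365, nLat]
  seasMonth <- rowsum(seasAll, .DOY_MONTH) / .MONTH_LENGTHS # [12, nLat]

  tmaxClim <- array(0, c(12L, nLat, nLon))
  for (i in seq_len(nLon)) {
    tmaxClim[, , i] <- seasMonth +
      matrix(config@tBase + config@trendDegCPerCentury[, i] * meanElapsed,
             12L, nLat, byrow = TRUE)
  }

  # RH has no seasonal cycle; average the clipped per-year values
  rhClim <- array(0, c(12L, nLat, nLon))
  for (i in seq_len(nLon)) {
    perYear <- outer(config@rhBase[, i],
                     (baseYears - config@years[1]) / 100 *
                       config@rhTrendPerCentury, "+")
    rowMean <- rowMeans(pmin(pmax(perYear, 0), 100))
    rhClim[, , i] <- matrix(rowMean, 12L, nLat, byrow = TRUE)
  }

  mk <- function(v, var) new("ClimatologyGrid", values = v, variable = var,
                             baseline = baseline,
                             lat = config@lat, lon = config@lon)
  list(tmax = mk(tmaxClim, "tmax"), rh = mk(rhClim, "rh"))
}
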