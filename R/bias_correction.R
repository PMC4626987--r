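# Mean-matching ("delta") bias correction.  Model monthly climatologies over
# a baseline window are compared with a reference climatology; temperature
# receives an additive correction, relative humidity a multiplicative one,
# and the correction is applied to every year of the record, not just the
# baseline.  Corrections are per calendar month with no smoothing across
# month boundaries.

#' Monthly climatology of a daily field
#'
#' For each calendar month and grid cell, the mean of all daily values in
#' that month over the baseline years.
#'
#' @param field a [GriddedDailyField] fully covering `baseline`.
#' @param baseline inclusive year range to average over (default 1961-1990).
#' @return A [ClimatologyGrid].
#' @examples
#' f <- getMember(generateEnsemble(
#'   synthConfig(nMembers = 1, years = c(1961, 1962), nLat = 2, nLon = 2)),
#'   "member1")$tmax
#' monthlyClimatology(f, c(1961, 1962))
#' @export
monthlyClimatology <- function(field, baseline = c(1961L, 1990L)) {
  stopifnot(is(field, "GriddedDailyField"))
  baseline <- .checkYearRange(baseline, "baseline")
  yrs <- field@years
  missing <- setdiff(seq.int(baseline[1], baseline[2]), seq.int(yrs[1], yrs[2]))
  if (length(missing))
    stop("field does not cover baseline years: ",
         paste(missing, collapse = ", "))
  axis <- .timeAxis(yrs)
  inBase <- axis$year >= baseline[1] & axis$year <= baseline[2]
  month <- axis$month[inBase]
  nLat <- length(field@lat); nLon <- length(field@lon)
  v <- field@values[inBase, , , drop = FALSE]
  dim(v) <- c(sum(inBase), nLat * nLon)
  sums <- rowsum(v, month)                       # [12, nCell]
  n <- as.numeric(table(factor(month, levels = 1:12)))
  clim <- sums / n
  dim(clim) <- c(12L, nLat, nLon)
  new("ClimatologyGrid", values = clim, variable = field@variable,
      baseline = baseline, lat = field@lat, lon = field@lon)
}

#' Bilinearly regrid a daily field onto a reference grid
#'
#' Each daily layer is interpolated bilinearly from the source grid to the
#' target cell centres.  Target cells outside the source grid's hull are
#' set missing.  A target identical to the source returns the input
#' unchanged.
#'
#' @param field a [GriddedDailyField].
#' @param targetLat,targetLon ascending target cell-centre coordinates.
#' @return A [GriddedDailyField] on the target grid.
#' @export
regridToReference <- function(field, targetLat, targetLon) {
  stopifnot(is(field, "GriddedDailyField"))
  targetLat <- sort(as.numeric(targetLat))
  targetLon <- sort(as.numeric(targetLon))
  if (identical(targetLat, field@lat) && identical(targetLon, field@lon))
    return(field)
  if (max(targetLat) < min(field@lat) || min(targetLat) > max(field@lat) ||
      max(targetLon) < min(field@lon) || min(targetLon) > max(field@lon))
    stop("target grid does not overlap the source grid")
  if (length(field@lat) < 2L || length(field@lon) < 2L)
    stop("bilinear regridding needs at least a 2 x 2 source grid")

  inLat <- targetLat >= min(field@lat) & targetLat <= max(field@lat)
  inLon <- targetLon >= min(field@lon) & targetLon <= max(field@lon)
  nT <- dim(field@values)[1]
  out <- array(NA_real_, c(nT, length(targetLat), length(targetLon)))
  tl <- targetLat[inLat]; tn <- targetLon[inLon]
  if (length(tl) && length(tn)) {
    # pracma::interp2 interpolates Z[length(y), length(x)] at (xp, yp)
    pts <- expand.grid(y = tl, x = tn)
    for (t in seq_len(nT)) {
      z <- pracma::interp2(x = field@lon, y = field@lat,
                           Z = field@values[t, , ],
                           xp = pts$x, yp = pts$y, method = "linear")
      out[t, inLat, inLon] <- matrix(z, length(tl), length(tn))
    }
  }
  new("GriddedDailyField", values = out, variable = field@variable,
      units = field@units, years = field@years,
      lat = targetLat, lon = targetLon)
}

#' Derive a monthly correction field
#'
#' Additive mode returns reference minus model per month and cell;
#' multiplicative mode returns reference over model, with cells of zero
#' model climatology set missing.
#'
#' @param modelClim,refClim [ClimatologyGrid]s for the same variable on the
#'   same grid.
#' @param mode `"additive"` or `"multiplicative"`.
#' @return A [CorrectionField].
#' @export
deriveCorrection <- function(modelClim, refClim,
                             mode = c("additive", "multiplicative")) {
  stopifnot(is(modelClim, "ClimatologyGrid"), is(refClim, "ClimatologyGrid"))
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(modelClim@lat, refClim@lat)) ||
      !isTRUE(all.equal(modelClim@lon, refClim@lon)))
    stop("model and reference climatologies are on different grids")
  if (!identical(modelClim@variable, refClim@variable))
    stop("model and reference climatologies describe different variables")
  if (mode == "additive") {
    corr <- refClim@values - modelClim@values
  } else {
    corr <- refClim@values / modelClim@values
    corr[modelClim@values == 0 | !is.finite(corr)] <- NA_real_
  }
  new("CorrectionField", values = corr, variable = modelClim@variable,
      mode = mode, lat = modelClim@lat, lon = modelClim@lon)
}

#' Apply a monthly correction to a daily field
#'
#' Every daily value is adjusted by its calendar month's correction layer
#' (added or multiplied), across the full record, not only the baseline.
#' Corrected relative humidity is clipped to [0, 100].  Cells whose
#' correction is missing become missing, with a warning.
#'
#' @param field a [GriddedDailyField] on the correction's grid.
#' @param corr a [CorrectionField] for the same variable.
#' @return The corrected [GriddedDailyField]; attribute `clippedFraction`
#'   records the share of values clipped (RH only), a QC metric.
#' @export
applyCorrection <- function(field, corr) {
  stopifnot(is(field, "GriddedDailyField"), is(corr, "CorrectionField"))
  if (!isTRUE(all.equal(field@lat, corr@lat)) ||
      !isTRUE(all.equal(field@lon, corr@lon)))
    stop("field and correction are on different grids")
  if (!identical(field@variable, corr@variable))
    warning("correction derived for variable '", corr@variable,
            "' applied to '", field@variable, "'")
  axis <- .timeAxis(field@years)
  nLat <- length(field@lat); nLon <- length(field@lon)
  nT <- length(axis$year)

  # expand monthly layers to the daily axis: [nT, nLat, nLon]
  daily <- corr@values[axis$month, , , drop = FALSE]
  if (anyNA(daily) && !anyNA(field@values))
    warning("missing correction for some cells/months; output set missing")
  out <- if (corr@mode == "additive") field@values + daily
         else field@values * daily
  clippedFraction <- 0
  if (identical(field@variable, "rh")) {
    clipped <- !is.na(out) & (out < 0 | out > 100)
    clippedFraction <- mean(clipped)
    out <- pmin(pmax(out, 0), 100)
  }
  res <- new("GriddedDailyField", values = out, variable = field@variable,
             units = field@units, years = field@years,
             lat = field@lat, lon = field@lon)
  attr(res, "clippedFraction") <- clippedFraction
  res
}

#' Bias-correct one ensemble member against a reference climatology
#'
#' Convenience wrapper: derives and applies an additive correction for
#' `tmax` and a multiplicative correction for `rh`, leaving `wind`
#' untouched (wind is not bias-corrected).
#'
#' @param member a list with `tmax`, `rh`, `wind` [GriddedDailyField]s.
#' @param reference named list of [ClimatologyGrid]s `tmax` and `rh`.
#' @param baseline inclusive baseline year range.
#' @return The member list with corrected `tmax` and `rh`.
#' @export
biasCorrectMember <- function(member, reference, baseline = c(1961L, 1990L)) {
  stopifnot(all(c("tmax", "rh", "wind") %in% names(member)),
            all(c("tmax", "rh") %in% names(reference)))
  tCorr <- deriveCorrection(monthlyClimatology(member$tmax, baseline),
                            reference$tmax, "additive")
  rCorr <- deriveCorrection(monthlyClimatology(member$rh, baseline),
                            reference$rh, "multiplicative")
  member$tmax <- applyCorrection(member$tmax, tCorr)
  member$rh <- applyCorrection(member$rh, rCorr)
  member
}
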