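# Trend characterisation of annual count series: centered 11-year moving
# average, ensemble percentile envelope (10th / median / 90th), average
# rate of increase over the smoothed span, and a Monte Carlo
# re-randomization trend test (values resampled with replacement, OLS
# slopes of the resampled series ranked against the observed slope).

#' Centered moving average of an annual series
#'
#' Unweighted centered mean over an odd window (default 11 years).  The
#' first and last `(window - 1) / 2` years have no output: a 1961-2100
#' input yields valid centres 1966-2095.
#'
#' @param values annual values.
#' @param years matching years (default consecutive from `startYear`).
#' @param window odd window length, `<=` series length.
#' @param startYear first year, used when `years` is missing.
#' @return List with `years` (valid centre years) and `values` (smoothed),
#'   class `"SmoothedSeries"`.
#' @examples
#' s <- movingAverage(rnorm(140, 50), startYear = 1961)
#' range(s$years)  # 1966 2095
#' @export
movingAverage <- function(values, years = NULL, window = 11L,
                          startYear = 1961L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  n <- length(values)
  if (n < window)
    stop("series length ", n, " is shorter than the window ", window)
  if (is.null(years)) years <- as.integer(startYear) + seq_len(n) - 1L
  if (length(years) != n) stop("years and values lengths differ")
  half <- (window - 1L) %/% 2L
  sm <- stats::filter(values, rep(1 / window, window), sides = 2)
  keep <- seq.int(half + 1L, n - half)
  structure(list(years = years[keep], values = as.numeric(sm[keep]),
                 window = window),
            class = "SmoothedSeries")
}

#' @export
print.SmoothedSeries <- function(x, ...) {
  cat(sprintf("SmoothedSeries: %d-year centered mean, centres %d-%d (%d values)\n",
              x$window, min(x$years), max(x$years), length(x$values)))
  invisible(x)
}

#' Ensemble percentile envelope
#'
#' Per-year order statistics across members: 10th percentile, median and
#' 90th percentile by default, with linear interpolation between order
#' statistics (type 7), so the median of six members is the mean of the
#' 3rd and 4th.
#'
#' @param memberSeries matrix `[member, year]`, or a list of equal-length
#'   numeric vectors on aligned years.
#' @param probs percentile probabilities in `[0, 1]`.
#' @param years optional year labels.
#' @return A data.frame with `year` and one column per percentile
#'   (`p10`, `p50`, `p90`, ...).
#' @export
ensemblePercentiles <- function(memberSeries, probs = c(0.1, 0.5, 0.9),
                                years = NULL) {
  if (is.list(memberSeries)) {
    len <- lengths(memberSeries)
    if (length(unique(len)) != 1L)
      stop("member series have different lengths (misaligned years)")
    memberSeries <- do.call(rbind, memberSeries)
  }
  if (nrow(memberSeries) < 2L) stop("at least 2 members required")
  q <- apply(memberSeries, 2, stats::quantile, probs = probs, type = 7,
             names = FALSE)
  if (length(probs) == 1L) q <- matrix(q, nrow = 1)
  out <- as.data.frame(t(q))
  names(out) <- paste0("p", round(probs * 100))
  out <- cbind(year = if (is.null(years)) seq_len(ncol(memberSeries)) else years,
               out)
  rownames(out) <- NULL
  out
}

#' Average rate of increase of a smoothed series
#'
#' Change in the smoothed value between the last and first valid centre,
#' divided by the span in years.  Two denominator conventions are exposed:
#' `"inclusive"` counts both end years (1966..2095 -> 130 years), matching
#' the convention in which the published rates were expressed;
#' `"difference"` uses the year difference (129), which recovers a linear
#' series' generating slope exactly.
#'
#' @param smoothed a `"SmoothedSeries"` from [movingAverage()], or a list
#'   with `years` and `values`.
#' @param denominator `"inclusive"` or `"difference"`.
#' @return Average rate in days/year.
#' @examples
#' s <- movingAverage(seq(0, 139), startYear = 1961)
#' averageRate(s, "difference")  # exactly 1
#' @export
averageRate <- function(smoothed, denominator = c("inclusive", "difference")) {
  denominator <- match.arg(denominator)
  yrs <- smoothed$years; val <- smoothed$values
  if (length(val) < 2L) stop("need at least 2 smoothed values")
  span <- yrs[length(yrs)] - yrs[1]
  denom <- if (denominator == "inclusive") span + 1L else span
  (val[length(val)] - val[1]) / denom
}

# OLS slope of y on x, closed form
.olsSlope <- function(y, x = seq_along(y)) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' Monte Carlo re-randomization trend test
#'
#' The observed trend statistic is the OLS slope of the series against its
#' year index.  The null distribution is built by resampling the observed
#' values with replacement (destroying order) `nIter` times and computing
#' each resample's slope.  The observed slope's rank among the null slopes
#' gives significance: one-sided (increasing) by default, a trend is
#' significant at level L% when the observed slope strictly exceeds at
#' least L% of the null slopes (ties count against significance).
#'
#' @param values numeric series (typically an 11-year-smoothed ensemble
#'   median of annual counts).
#' @param nIter number of resamples (default 1000).
#' @param seed RNG seed.
#' @param levels confidence levels in percent.
#' @param alternative `"greater"` (increasing) or `"two.sided"` (ranks
#'   absolute slopes).
#' @param years optional time axis; defaults to the series index.
#' @param rate optional pre-computed average rate stored in the result.
#' @return A [TrendTest].
#' @examples
#' monteCarloTrendTest(seq_len(131), nIter = 200, seed = 7)
#' @export
monteCarloTrendTest <- function(values, nIter = 1000L, seed = 1L,
                                levels = c(90, 95, 99),
                                alternative = c("greater", "two.sided"),
                                years = NULL, rate = NA_real_) {
  alternative <- match.arg(alternative)
  nIter <- as.integer(nIter)
  n <- length(values)
  if (n < 10L) stop("series too short for a trend test (need >= 10)")
  if (nIter < 100L) stop("nIter must be >= 100")
  if (anyNA(values)) stop("series contains missing values")
  x <- if (is.null(years)) seq_len(n) else as.numeric(years)
  obs <- .olsSlope(values, x)
  levels <- sort(levels)

  if (stats::var(values) == 0) {
    # constant series: zero slope, nothing to resample
    return(new("TrendTest", slope = 0, rate = rate, exceedFraction = 0,
               significant = stats::setNames(rep(FALSE, length(levels)),
                                             paste0("p", levels)),
               levels = levels, nIter = nIter, seed = as.integer(seed),
               alternative = alternative))
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  idx <- sample.int(n, n * nIter, replace = TRUE)
  resamples <- matrix(values[idx], n, nIter)
  xc <- x - mean(x)
  nullSlopes <- as.numeric(crossprod(xc, resamples)) / sum(xc * xc)

  if (alternative == "two.sided") {
    exceed <- mean(abs(nullSlopes) < abs(obs))
  } else {
    exceed <- mean(nullSlopes < obs)
  }
  sig <- stats::setNames(exceed >= levels / 100, paste0("p", levels))
  new("TrendTest", slope = obs, rate = rate, exceedFraction = exceed,
      significant = sig, levels = levels, nIter = nIter,
      seed = as.integer(seed), alternative = alternative)
}

#' Per-cell trend map of an annual count grid
#'
#' For each cell of (typically) the ensemble-median annual count grid:
#' smooth with the centered moving average, compute the average rate, and
#' run the Monte Carlo trend test on the smoothed series.  Cells whose
#' raw series is structurally constant at 0 or 365 days/year can exhibit
#' no trend and are flagged `-1` ("no trend possible") rather than
#' non-significant.
#'
#' @param counts an [AnnualCountGrid] (e.g. ensemble median).
#' @param window moving-average window (odd, default 11).
#' @param nIter,seed Monte Carlo settings.
#' @param levels confidence levels in percent.
#' @param denominator rate denominator convention, see [averageRate()].
#' @param alternative test sidedness, see [monteCarloTrendTest()].
#' @param smooth set `FALSE` to test the raw annual series.
#' @return A [TrendGrid].
#' @export
trendMap <- function(counts, window = 11L, nIter = 1000L, seed = 1L,
                     levels = c(90, 95, 99),
                     denominator = c("inclusive", "difference"),
                     alternative = c("greater", "two.sided"),
                     smooth = TRUE) {
  stopifnot(is(counts, "AnnualCountGrid"))
  denominator <- match.arg(denominator)
  alternative <- match.arg(alternative)
  nLat <- length(counts@lat); nLon <- length(counts@lon)
  yrs <- seq.int(counts@years[1], counts@years[2])
  rate <- matrix(NA_real_, nLat, nLon)
  flag <- matrix(0L, nLat, nLon)
  cellSeed <- as.integer(seed)
  for (j in seq_len(nLat)) {
    for (i in seq_len(nLon)) {
      series <- counts@counts[, j, i]
      if (anyNA(series)) { flag[j, i] <- 0L; next }
      if (all(series == 0) || all(series == .DAYS_PER_YEAR)) {
        rate[j, i] <- 0
        flag[j, i] <- -1L
        next
      }
      sm <- if (smooth) movingAverage(series, years = yrs, window = window)
            else list(years = yrs, values = as.numeric(series))
      rate[j, i] <- averageRate(sm, denominator)
      tt <- monteCarloTrendTest(sm$values, nIter = nIter, seed = cellSeed,
                                levels = levels, alternative = alternative,
                                years = sm$years)
      sigLevels <- tt@levels[tt@significant]
      flag[j, i] <- if (length(sigLevels)) as.integer(max(sigLevels)) else 0L
      cellSeed <- cellSeed + 1L
    }
  }
  new("TrendGrid", rate = rate, flag = flag, category = counts@category,
      nIter = as.integer(nIter), seed = as.integer(seed),
      lat = counts@lat, lon = counts@lon)
}

#' Ensemble median of annual count grids
#'
#' Per cell-year median across members (type-7 interpolation, so the
#' median of six members is the mean of the 3rd and 4th order statistics).
#'
#' @param countList list of [AnnualCountGrid]s for the same category,
#'   one per member.
#' @return An [AnnualCountGrid] of (possibly fractional) median counts.
#' @export
ensembleMedianCounts <- function(countList) {
  stopifnot(length(countList) >= 1L,
            all(vapply(countList, is, logical(1), "AnnualCountGrid")))
  c1 <- countList[[1]]
  arr <- vapply(countList, fieldValues,
                array(0, dim(c1@counts)))           # [year, lat, lon, member]
  med <- apply(arr, c(1, 2, 3), stats::median)
  dimnames(med) <- NULL
  new("AnnualCountGrid", counts = med, category = c1@category,
      years = c1@years, lat = c1@lat, lon = c1@lon)
}
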