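# Heat-day classification against the US National Weather Service
# apparent-temperature symptom chart.  Nested "hot day" categories count
# days with ATmax at or above 27/32/39/51 degC (Hda2-Hda5; Hda1 is the
# complement below 27), and four disjoint symptom bands partition
# [27, Inf): I Caution [27, 32), II Extreme Caution [32, 39),
# III Danger [39, 51), IV Extreme Danger [51, Inf).  All thresholds are
# inclusive on the left.

#' Threshold scheme for hot days and symptom bands
#'
#' @param hda named thresholds (degC) for the nested hot-day categories;
#'   Hda1 is implicitly `< ` the first threshold.
#' @return A list with components `hda` (named numeric) and `bandEdges`
#'   (band boundaries, last edge `Inf`), class `"ThresholdScheme"`.
#' @examples
#' thresholdScheme()
#' @export
thresholdScheme <- function(hda = c(Hda2 = 27, Hda3 = 32, Hda4 = 39, Hda5 = 51)) {
  if (is.unsorted(hda, strictly = TRUE))
    stop("hot-day thresholds must be strictly increasing")
  structure(
    list(hda = hda, bandEdges = c(unname(hda), Inf),
         bandNames = paste0("Band", c("I", "II", "III", "IV")[seq_along(hda)])),
    class = "ThresholdScheme")
}

#' @export
print.ThresholdScheme <- function(x, ...) {
  cat("ThresholdScheme:\n  hot days:",
      paste(sprintf("%s >= %g", names(x$hda), x$hda), collapse = ", "),
      sprintf("(Hda1 < %g)\n", x$hda[1]),
      " bands:",
      paste(sprintf("%s [%g, %g)", x$bandNames, utils::head(x$bandEdges, -1),
                    utils::tail(x$bandEdges, -1)), collapse = ", "), "\n")
  invisible(x)
}

#' Classify one or more daily ATmax values
#'
#' Returns the hot-day memberships (all satisfied nested categories) and
#' the single symptom band (or none below the first threshold) for each
#' value.  Thresholds are inclusive on the left: ATmax = 32 is Hda2 and
#' Hda3 and falls in Band II.
#'
#' @param atmax numeric vector of daily maximum apparent temperatures, degC.
#' @param scheme a [thresholdScheme()].
#' @return A data.frame with one logical column per hot-day category
#'   (`Hda1..Hda5`) and a factor column `band` (levels BandI..BandIV,
#'   `NA` below the first threshold or for missing input).
#' @examples
#' classifyDay(c(26.9, 32, 51))
#' @export
classifyDay <- function(atmax, scheme = thresholdScheme()) {
  hda <- scheme$hda
  out <- data.frame(Hda1 = !is.na(atmax) & atmax < hda[1])
  for (k in seq_along(hda))
    out[[names(hda)[k]]] <- !is.na(atmax) & atmax >= hda[k]
  band <- cut(atmax, breaks = c(-Inf, scheme$bandEdges), right = FALSE,
              labels = c("none", scheme$bandNames))
  band[band == "none"] <- NA
  out$band <- factor(as.character(band), levels = scheme$bandNames)
  out
}

#' Annual hot-day and symptom-band counts per grid cell
#'
#' Counts, for every calendar year and cell, the days in each hot-day
#' category and each symptom band.  Years are calendar years on the
#' 365-day axis, so the conservation identities `Hda1 + Hda2 = 365` and
#' `BandI + ... + BandIV = Hda2` hold exactly for complete data; both are
#' asserted on every call.  Cell-years containing missing days are set
#' missing with a warning rather than rescaled.
#'
#' @param atmax a [GriddedDailyField] of daily maximum apparent
#'   temperature (variable `atmax`).
#' @param scheme a [thresholdScheme()].
#' @return Named list of [AnnualCountGrid]s: `Hda1..Hda5`, `BandI..BandIV`.
#' @examples
#' ens <- generateEnsemble(synthConfig(nMembers = 1, years = c(1961, 1963),
#'                                     nLat = 2, nLon = 2))
#' m <- getMember(ens, "member1")
#' counts <- annualCounts(dailyATMax(m$tmax, m$rh, m$wind))
#' counts$Hda2
#' @export
annualCounts <- function(atmax, scheme = thresholdScheme()) {
  stopifnot(is(atmax, "GriddedDailyField"))
  axis <- .timeAxis(atmax@years)
  nYear <- length(axis$years)
  nLat <- length(atmax@lat); nLon <- length(atmax@lon)
  nCell <- nLat * nLon
  v <- atmax@values
  dim(v) <- c(.DAYS_PER_YEAR, nYear, nCell)

  yearGroup <- rep(seq_len(nYear), each = .DAYS_PER_YEAR)
  countIf <- function(test) {
    x <- test
    dim(x) <- c(.DAYS_PER_YEAR * nYear, nCell)
    cnt <- rowsum(x + 0L, yearGroup)                 # [nYear, nCell]
    dim(cnt) <- c(nYear, nLat, nLon)
    cnt
  }

  bad <- is.na(v)
  anyBad <- apply(bad, c(2, 3), any)                 # [nYear, nCell]
  if (any(anyBad))
    warning(sum(anyBad), " cell-year(s) with missing days excluded from counts")

  hda <- scheme$hda
  res <- list()
  res$Hda1 <- countIf(!bad & v < hda[1])
  for (k in seq_along(hda))
    res[[names(hda)[k]]] <- countIf(!bad & v >= hda[k])
  edges <- scheme$bandEdges
  for (k in seq_along(scheme$bandNames))
    res[[scheme$bandNames[k]]] <-
      countIf(!bad & v >= edges[k] & v < edges[k + 1])

  res <- lapply(res, function(cnt) {
    cnt[as.vector(anyBad)] <- NA_integer_
    cnt
  })

  # conservation and nesting, asserted on every run
  ok <- !anyBad
  stopifnot(all((res$Hda1 + res[[names(hda)[1]]])[ok] == .DAYS_PER_YEAR))
  bandSum <- Reduce(`+`, res[scheme$bandNames])
  stopifnot(all(bandSum[ok] == res[[names(hda)[1]]][ok]))
  for (k in seq_along(hda)[-1])
    stopifnot(all(res[[names(hda)[k - 1]]][ok] >= res[[names(hda)[k]]][ok]))

  mk <- function(cnt, label)
    new("AnnualCountGrid", counts = cnt, category = label,
        years = atmax@years, lat = atmax@lat, lon = atmax@lon)
  mapply(mk, res, names(res), SIMPLIFY = FALSE)
}

#' Mean annual count over a time slice
#'
#' Per-cell arithmetic mean of the annual counts over an inclusive slice
#' of years (typically a 30-year window).
#'
#' @param counts an [AnnualCountGrid].
#' @param slice inclusive year range, fully covered by `counts`.
#' @return A [TimeSliceSummary].
#' @export
timesliceMean <- function(counts, slice) {
  stopifnot(is(counts, "AnnualCountGrid"))
  slice <- .checkYearRange(slice, "slice")
  yrs <- seq.int(counts@years[1], counts@years[2])
  if (slice[1] < yrs[1] || slice[2] > yrs[length(yrs)])
    stop("slice ", slice[1], "-", slice[2],
         " is not fully covered by the count years ",
         yrs[1], "-", yrs[length(yrs)])
  sel <- yrs >= slice[1] & yrs <= slice[2]
  m <- apply(counts@counts[sel, , , drop = FALSE], c(2, 3), mean)
  new("TimeSliceSummary", values = m, slice = slice,
      category = counts@category, lat = counts@lat, lon = counts@lon)
}

#' Ensemble average of per-member time-slice summaries
#'
#' Mean of member means: each member is summarised first, then the
#' summaries are averaged, matching the convention of analysing the
#' ensemble average of per-member statistics.
#'
#' @param summaries list of [TimeSliceSummary]s on the same grid/slice.
#' @return A [TimeSliceSummary].
#' @export
ensembleMeanSummary <- function(summaries) {
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, is, logical(1), "TimeSliceSummary")))
  s1 <- summaries[[1]]
  vals <- Reduce(`+`, lapply(summaries, fieldValues)) / length(summaries)
  new("TimeSliceSummary", values = vals, slice = s1@slice,
      category = s1@category, lat = s1@lat, lon = s1@lon)
}

#' Change map between two time slices
#'
#' Per-cell `future - baseline` mean days/year.  Adding the returned delta
#' back to the baseline reconstructs the future total.
#'
#' @param future,baseline [TimeSliceSummary]s for the same category and grid.
#' @return Numeric matrix `[lat, lon]` of deltas (days/year).
#' @export
changeMap <- function(future, baseline) {
  stopifnot(is(future, "TimeSliceSummary"), is(baseline, "TimeSliceSummary"))
  if (!isTRUE(all.equal(future@lat, baseline@lat)) ||
      !isTRUE(all.equal(future@lon, baseline@lon)))
    stop("time slices are on different grids")
  if (!identical(future@category, baseline@category))
    stop("time slices summarise different categories")
  future@values - baseline@values
}
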