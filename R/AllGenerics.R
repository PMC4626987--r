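#' Grid and data accessors
#'
#' Accessor generics for the gridded containers: `gridLat()` / `gridLon()`
#' return cell-centre coordinates, `fieldValues()` the underlying numeric
#' array, `fieldYears()` the inclusive year range, and `varName()` the
#' variable or category label.
#'
#' @param x a heatband container object.
#' @return `gridLat`/`gridLon`: numeric vectors; `fieldValues`: the data
#'   array; `fieldYears`: integer length-2; `varName`: character scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridLat", function(x) standardGeneric("gridLat"))
#' @rdname accessors
#' @export
setGeneric("gridLon", function(x) standardGeneric("gridLon"))
#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("fieldYears", function(x) standardGeneric("fieldYears"))
#' @rdname accessors
#' @export
setGeneric("varName", function(x) standardGeneric("varName"))

#' @rdname accessors
setMethod("gridLat", "GriddedDailyField", function(x) x@lat)
#' @rdname accessors
setMethod("gridLon", "GriddedDailyField", function(x) x@lon)
#' @rdname accessors
setMethod("fieldValues", "GriddedDailyField", function(x) x@values)
#' @rdname accessors
setMethod("fieldYears", "GriddedDailyField", function(x) x@years)
#' @rdname accessors
setMethod("varName", "GriddedDailyField", function(x) x@variable)

#' @rdname accessors
setMethod("gridLat", "ClimatologyGrid", function(x) x@lat)
#' @rdname accessors
setMethod("gridLon", "ClimatologyGrid", function(x) x@lon)
#' @rdname accessors
setMethod("fieldValues", "ClimatologyGrid", function(x) x@values)
#' @rdname accessors
setMethod("varName", "ClimatologyGrid", function(x) x@variable)

#' @rdname accessors
setMethod("gridLat", "CorrectionField", function(x) x@lat)
#' @rdname accessors
setMethod("gridLon", "CorrectionField", function(x) x@lon)
#' @rdname accessors
setMethod("fieldValues", "CorrectionField", function(x) x@values)
#' @rdname accessors
setMethod("varName", "CorrectionField", function(x) x@variable)

#' @rdname accessors
setMethod("gridLat", "AnnualCountGrid", function(x) x@lat)
#' @rdname accessors
setMethod("gridLon", "AnnualCountGrid", function(x) x@lon)
#' @rdname accessors
setMethod("fieldValues", "AnnualCountGrid", function(x) x@counts)
#' @rdname accessors
setMethod("fieldYears", "AnnualCountGrid", function(x) x@years)
#' @rdname accessors
setMethod("varName", "AnnualCountGrid", function(x) x@category)

#' @rdname accessors
setMethod("gridLat", "TimeSliceSummary", function(x) x@lat)
#' @rdname accessors
setMethod("gridLon", "TimeSliceSummary", function(x) x@lon)
#' @rdname accessors
setMethod("fieldValues", "TimeSliceSummary", function(x) x@values)
#' @rdname accessors
setMethod("varName", "TimeSliceSummary", function(x) x@category)

#' Ensemble accessors
#'
#' @param x a [ClimateEnsemble].
#' @param i member name or index.
#' @return `ensembleMembers()`: named list of member bundles;
#'   `memberNames()`: character vector; `getMember()`: one bundle (a list
#'   with `tmax`, `rh`, `wind`).
#' @name ensemble-accessors
NULL

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))
#' @rdname ensemble-accessors
setMethod("ensembleMembers", "ClimateEnsemble", function(x) x@members)

#' @rdname ensemble-accessors
#' @export
setGeneric("memberNames", function(x) standardGeneric("memberNames"))
#' @rdname ensemble-accessors
setMethod("memberNames", "ClimateEnsemble", function(x) names(x@members))

#' @rdname ensemble-accessors
#' @export
getMember <- function(x, i) {
  stopifnot(is(x, "ClimateEnsemble"))
  m <- x@members[[i]]
  if (is.null(m)) stop("no such ensemble member: ", i)
  m
}

setMethod("show", "GriddedDailyField", function(object) {
  cat(sprintf(
    "GriddedDailyField '%s' [%s]\n  %d days (%d-%d, 365-day calendar), %d x %d grid\n  lat %.2f..%.2f, lon %.2f..%.2f\n",
    object@variable, object@units, dim(object@values)[1],
    object@years[1], object@years[2],
    length(object@lat), length(object@lon),
    min(object@lat), max(object@lat), min(object@lon), max(object@lon)
  ))
})

setMethod("show", "ClimatologyGrid", function(object) {
  cat(sprintf(
    "ClimatologyGrid '%s': 12 monthly layers, %d x %d grid, baseline %d-%d\n",
    object@variable, length(object@lat), length(object@lon),
    object@baseline[1], object@baseline[2]
  ))
})

setMethod("show", "CorrectionField", function(object) {
  cat(sprintf(
    "CorrectionField '%s' (%s): 12 monthly layers, %d x %d grid\n",
    object@variable, object@mode, length(object@lat), length(object@lon)
  ))
})

setMethod("show", "ClimateEnsemble", function(object) {
  m1 <- object@members[[1]]$tmax
  cat(sprintf(
    "ClimateEnsemble: %d member(s) [%s]\n  each with tmax/rh/wind, %d-%d on a %d x %d grid\n",
    length(object@members), paste(names(object@members), collapse = ", "),
    m1@years[1], m1@years[2], length(m1@lat), length(m1@lon)
  ))
})

setMethod("show", "AnnualCountGrid", function(object) {
  cat(sprintf(
    "AnnualCountGrid '%s': years %d-%d, %d x %d grid\n",
    object@category, object@years[1], object@years[2],
    length(object@lat), length(object@lon)
  ))
})

setMethod("show", "TimeSliceSummary", function(object) {
  cat(sprintf(
    "TimeSliceSummary '%s' %d-%d: mean days/year, range %.1f..%.1f\n",
    object@category, object@slice[1], object@slice[2],
    min(object@values, na.rm = TRUE), max(object@values, na.rm = TRUE)
  ))
})

setMethod("show", "TrendTest", function(object) {
  sig <- paste(sprintf("%d%%:%s", object@levels,
                       ifelse(object@significant, "yes", "no")), collapse = " ")
  cat(sprintf(
    "TrendTest: slope %.4g, rate %.4g days/year, exceed %.3f (%s, %d resamples)\n  significant at %s\n",
    object@slope, object@rate, object@exceedFraction, object@alternative,
    object@nIter, sig
  ))
})

setMethod("show", "TrendGrid", function(object) {
  tab <- table(factor(object@flag, levels = c(-1, 0, 90, 95, 99)))
  cat(sprintf(
    "TrendGrid '%s' (%d resamples): %d x %d cells\n  flags: no-trend-possible %d, n.s. %d, 90%% %d, 95%% %d, 99%% %d\n",
    object@category, object@nIter, length(object@lat), length(object@lon),
    tab[["-1"]], tab[["0"]], tab[["90"]], tab[["95"]], tab[["99"]]
  ))
})
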