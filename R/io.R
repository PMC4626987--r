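# Plain-text persistence.  Gridded objects are stored as CSV with a short
# commented header carrying the grid and calendar metadata, one column per
# grid cell (column cNNN in lat-major cell order) and one row per time
# step.  Self-describing, diff-able, and readable by any CSV tool.

.writeMetaCSV <- function(path, meta, body) {
  hdr <- vapply(names(meta), function(k)
    sprintf("#%s=%s", k, paste(meta[[k]], collapse = ",")), character(1))
  writeLines(hdr, path)
  data.table::fwrite(body, path, append = TRUE, col.names = TRUE)
}

.readMetaCSV <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    k <- sub("=.*$", "", kv)
    meta[[k]] <- strsplit(sub("^[^=]*=", "", kv), ",", fixed = TRUE)[[1]]
  }
  body <- data.table::fread(path, skip = length(hdr), header = TRUE,
                            data.table = FALSE)
  list(meta = meta, body = body)
}

.cellCols <- function(n) sprintf("c%03d", seq_len(n))

#' Write / read a daily field as headered CSV
#'
#' One row per day (`year`, `doy` columns) and one column per grid cell in
#' lat-major order; grid and variable metadata in commented header lines.
#'
#' @param field a [GriddedDailyField].
#' @param path file path.
#' @return `writeDailyField`: the path, invisibly. `readDailyField`: the
#'   reconstructed [GriddedDailyField].
#' @export
writeDailyField <- function(field, path) {
  stopifnot(is(field, "GriddedDailyField"))
  axis <- .timeAxis(field@years)
  nCell <- length(field@lat) * length(field@lon)
  v <- field@values
  dim(v) <- c(length(axis$year), nCell)
  body <- data.frame(year = axis$year, doy = axis$doy)
  body[.cellCols(nCell)] <- as.data.frame(v)
  .writeMetaCSV(path, list(
    class = "GriddedDailyField", variable = field@variable,
    units = field@units, years = field@years,
    lat = field@lat, lon = field@lon, calendar = "365_day"), body)
  invisible(path)
}

#' @rdname writeDailyField
#' @export
readDailyField <- function(path) {
  r <- .readMetaCSV(path)
  lat <- as.numeric(r$meta$lat); lon <- as.numeric(r$meta$lon)
  years <- as.integer(r$meta$years)
  v <- as.matrix(r$body[.cellCols(length(lat) * length(lon))])
  dim(v) <- c(nrow(r$body), length(lat), length(lon))
  dimnames(v) <- NULL
  new("GriddedDailyField", values = v, variable = r$meta$variable,
      units = r$meta$units, years = years, lat = lat, lon = lon)
}

#' Write / read a monthly climatology as headered CSV
#'
#' @param clim a [ClimatologyGrid].
#' @param path file path.
#' @return `writeClimatology`: the path, invisibly; `readClimatology`: a
#'   [ClimatologyGrid].
#' @export
writeClimatology <- function(clim, path) {
  stopifnot(is(clim, "ClimatologyGrid"))
  nCell <- length(clim@lat) * length(clim@lon)
  v <- clim@values
  dim(v) <- c(12L, nCell)
  body <- data.frame(month = 1:12)
  body[.cellCols(nCell)] <- as.data.frame(v)
  .writeMetaCSV(path, list(
    class = "ClimatologyGrid", variable = clim@variable,
    baseline = clim@baseline, lat = clim@lat, lon = clim@lon), body)
  invisible(path)
}

#' @rdname writeClimatology
#' @export
readClimatology <- function(path) {
  r <- .readMetaCSV(path)
  lat <- as.numeric(r$meta$lat); lon <- as.numeric(r$meta$lon)
  v <- as.matrix(r$body[.cellCols(length(lat) * length(lon))])
  dim(v) <- c(12L, length(lat), length(lon))
  dimnames(v) <- NULL
  new("ClimatologyGrid", values = v, variable = r$meta$variable,
      baseline = as.integer(r$meta$baseline), lat = lat, lon = lon)
}

#' Write / read an annual count grid as headered CSV
#'
#' @param counts an [AnnualCountGrid].
#' @param path file path.
#' @return `writeAnnualCounts`: the path, invisibly; `readAnnualCounts`:
#'   an [AnnualCountGrid].
#' @export
writeAnnualCounts <- function(counts, path) {
  stopifnot(is(counts, "AnnualCountGrid"))
  nCell <- length(counts@lat) * length(counts@lon)
  yrs <- seq.int(counts@years[1], counts@years[2])
  v <- counts@counts
  dim(v) <- c(length(yrs), nCell)
  body <- data.frame(year = yrs)
  body[.cellCols(nCell)] <- as.data.frame(v)
  .writeMetaCSV(path, list(
    class = "AnnualCountGrid", category = counts@category,
    years = counts@years, lat = counts@lat, lon = counts@lon), body)
  invisible(path)
}

#' @rdname writeAnnualCounts
#' @export
readAnnualCounts <- function(path) {
  r <- .readMetaCSV(path)
  lat <- as.numeric(r$meta$lat); lon <- as.numeric(r$meta$lon)
  v <- as.matrix(r$body[.cellCols(length(lat) * length(lon))])
  dim(v) <- c(nrow(r$body), length(lat), length(lon))
  dimnames(v) <- NULL
  new("AnnualCountGrid", counts = v, category = r$meta$category,
      years = as.integer(r$meta$years), lat = lat, lon = lon)
}
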