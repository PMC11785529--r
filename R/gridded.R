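#' Construct a gridded time series
#'
#' A `gridded_series` is a `(time, lat, lon)` array with units, a missing
#' mask (encoded as `NA`), its [grid_spec()] and a cadence tag. Sub-annual
#' cadences carry a `time` data frame mapping each slice to a calendar year
#' (and step within year); annual series use the grid's year axis directly.
#'
#' @param values Numeric array `(n_time, n_lat, n_lon)`; `NA` marks missing.
#' @param grid A [grid_spec()].
#' @param units Units string (CF style, e.g. `"mg C m-2 d-1"`).
#' @param cadence One of `"annual"`, `"monthly"`, `"8-day"`.
#' @param name Variable name (e.g. `"npp"`).
#' @param time For sub-annual cadences, a data frame with columns `year` and
#'   `step`, one row per time slice; ignored for annual cadence.
#' @return An object of class `gridded_series`.
#' @export
gridded_series <- function(values, grid, units = "1", cadence = "annual",
                           name = "field", time = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.array(values),
            length(dim(values)) == 3L)
  cadence <- match.arg(cadence, c("annual", "monthly", "8-day"))
  d <- dim(values)
  if (d[2] != length(grid$lat) || d[3] != length(grid$lon))
    stop("values shape does not match grid", call. = FALSE)
  if (cadence == "annual") {
    if (d[1] != length(grid$years))
      stop("annual series must have one slice per grid year", call. = FALSE)
    time <- data.frame(year = grid$years, step = 1L)
  } else {
    if (is.null(time) || nrow(time) != d[1])
      stop("sub-annual series needs a time table with one row per slice",
           call. = FALSE)
    if (is.unsorted(time$year)) stop("time axis must be sorted", call. = FALSE)
  }
  structure(list(values = values, grid = grid, units = units,
                 cadence = cadence, name = name, time = time),
            class = "gridded_series")
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf("<gridded_series> %s [%s], %s cadence, %d x %d x %d, %.1f%% missing\n",
              x$name, x$units, x$cadence,
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              100 * mean(is.na(x$values))))
  invisible(x)
}

# pull the 1-D time series of one cell
cell_series <- function(series, i, j) series$values[, i, j]

#' Write a gridded dataset to a self-describing text file
#'
#' Serialises one or more [gridded_series()] sharing a grid into a single
#' CF-like JSON container: coordinate variables (`lat`, `lon`, `years`),
#' per-variable units and cadence, and missing values stored as `null`.
#' Floats are written at full precision so a write/read round trip
#' reproduces the data exactly to stored precision.
#'
#' @param dataset A named list of `gridded_series` (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_gridded()]
#' @export
write_gridded <- function(dataset, path) {
  if (inherits(dataset, "gridded_series"))
    dataset <- stats::setNames(list(dataset), dataset$name)
  stopifnot(length(dataset) > 0, all(vapply(dataset, inherits, TRUE,
                                            "gridded_series")))
  g <- dataset[[1]]$grid
  vars <- lapply(dataset, function(s) {
    list(units = s$units, cadence = s$cadence, name = s$name,
         time_year = s$time$year, time_step = s$time$step,
         dim = dim(s$values), values = as.vector(s$values))
  })
  obj <- list(format = "npprank-gridded-1",
              lat = g$lat, lon = g$lon, years = g$years,
              land_mask = as.vector(g$land_mask),
              variables = vars)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a gridded dataset written by [write_gridded()]
#'
#' @param path File path.
#' @return A named list of [gridded_series()].
#' @export
read_gridded <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed gridded file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "npprank-gridded-1"))
    stop("malformed gridded file '", path, "': missing format tag",
         call. = FALSE)
  grid <- grid_spec(obj$lat, obj$lon, obj$years,
                    matrix(obj$land_mask, length(obj$lat), length(obj$lon)))
  out <- lapply(obj$variables, function(v) {
    if (is.null(v$units)) warning("variable without units attribute")
    vals <- array(as.numeric(v$values), dim = v$dim)
    tm <- NULL
    if (!identical(v$cadence, "annual"))
      tm <- data.frame(year = as.integer(v$time_year),
                       step = as.integer(v$time_step))
    gridded_series(vals, grid, units = if (is.null(v$units)) "1" else v$units,
                   cadence = v$cadence, name = v$name, time = tm)
  })
  names(out) <- names(obj$variables)
  out
}
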