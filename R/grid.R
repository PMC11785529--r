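#' Define a regular latitude-longitude grid with a land mask
#'
#' A `grid_spec` carries the cell-centre coordinates, the annual time axis and
#' the land mask shared by every gridded field in an analysis. Latitudes must
#' lie strictly inside (-90, 90) so that `cos(lat)` cell-area weights are
#' positive everywhere.
#'
#' @param lat Numeric vector of cell-centre latitudes (degrees north),
#'   strictly increasing, strictly within (-90, 90).
#' @param lon Numeric vector of cell-centre longitudes (degrees east),
#'   strictly increasing.
#' @param years Integer vector of consecutive calendar years (>= 2).
#' @param land_mask Logical matrix `length(lat) x length(lon)`; `TRUE` marks
#'   land (excluded from all analyses). Default: all ocean.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(lat = seq(-60, 60, by = 20), lon = seq(-170, 170, by = 40),
#'                years = 1998:2023)
#' g
#' @export
grid_spec <- function(lat, lon, years, land_mask = NULL) {
  stopifnot(is.numeric(lat), is.numeric(lon))
  if (any(lat <= -90) || any(lat >= 90))
    stop("latitudes must lie strictly within (-90, 90)", call. = FALSE)
  if (is.unsorted(lat, strictly = TRUE))
    stop("latitudes must be strictly increasing", call. = FALSE)
  years <- as.integer(years)
  if (length(years) < 2L)
    stop("need at least 2 years", call. = FALSE)
  if (any(diff(years) != 1L))
    stop("years must be consecutive", call. = FALSE)
  if (is.null(land_mask))
    land_mask <- matrix(FALSE, length(lat), length(lon))
  stopifnot(is.logical(land_mask),
            nrow(land_mask) == length(lat), ncol(land_mask) == length(lon))
  if (all(land_mask))
    stop("grid needs at least one ocean cell", call. = FALSE)
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 years = years, land_mask = land_mask),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d lat x %d lon, years %d-%d, %d ocean cells\n",
              length(x$lat), length(x$lon), min(x$years), max(x$years),
              sum(!x$land_mask)))
  invisible(x)
}

n_cells <- function(grid) length(grid$lat) * length(grid$lon)

#' Latitude-dependent area weights
#'
#' Cell area on a regular grid is proportional to the cosine of latitude; the
#' weights are normalised to sum to one over ocean cells, so area-weighted
#' spatial means are plain weighted averages. Land cells get weight zero.
#'
#' @param grid A [grid_spec()].
#' @return A `length(lat) x length(lon)` numeric matrix summing to 1 over
#'   ocean cells, of class `area_weights`.
#' @examples
#' g <- grid_spec(lat = c(0, 60), lon = 0, years = 1998:1999)
#' area_weights(g)   # cos ratio 1 : 0.5 -> weights 2/3, 1/3
#' @export
area_weights <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  w <- matrix(cos(grid$lat * pi / 180), length(grid$lat), length(grid$lon))
  w[grid$land_mask] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("all-land grid: no ocean area", call. = FALSE)
  structure(w / tot, class = c("area_weights", "matrix"))
}

#' Build a latitude-band biome mask
#'
#' Partitions the ocean into `n_biomes` contiguous latitude bands of (near)
#' equal row count and computes each band's areal proportion of the global
#' ocean from cos(latitude) cell areas. This is a synthetic stand-in for an
#' observed ocean-biome classification: the downstream distribution
#' comparison only requires labels plus areal proportions.
#'
#' @param grid A [grid_spec()].
#' @param n_biomes Number of latitude bands, between 1 and `length(grid$lat)`.
#' @param seed Unused (bands are deterministic); accepted for interface
#'   symmetry with the other generators.
#' @return A `biome_mask`: list with `labels` (integer matrix, `NA` on land)
#'   and `proportions` (named numeric, sums to 1).
#' @examples
#' g <- grid_spec(lat = seq(-50, 50, by = 20), lon = seq(0, 300, by = 60),
#'                years = 1998:2000)
#' b <- make_biome_mask(g, n_biomes = 3)
#' sum(b$proportions)
#' @export
make_biome_mask <- function(grid, n_biomes, seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  nlat <- length(grid$lat)
  if (n_biomes < 1L || n_biomes > nlat)
    stop("n_biomes must be between 1 and the number of latitude rows",
         call. = FALSE)
  band <- if (n_biomes == 1L) rep(1L, nlat) else
    as.integer(cut(seq_len(nlat), breaks = n_biomes, labels = FALSE))
  labels <- matrix(band, nlat, length(grid$lon))
  labels[grid$land_mask] <- NA_integer_
  area <- matrix(cos(grid$lat * pi / 180), nlat, length(grid$lon))
  area[grid$land_mask] <- 0
  prop <- vapply(seq_len(n_biomes),
                 function(b) sum(area[which(!grid$land_mask & labels == b)]),
                 numeric(1))
  prop <- prop / sum(prop)
  names(prop) <- as.character(seq_len(n_biomes))
  structure(list(labels = labels, proportions = prop), class = "biome_mask")
}

#' @export
print.biome_mask <- function(x, ...) {
  cat("<biome_mask>", length(x$proportions), "latitude-band biomes\n")
  print(round(x$proportions, 4))
  invisible(x)
}
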