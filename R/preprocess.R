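#' Reduce a sub-annual gridded series to annual means
#'
#' Per pixel and year, the unweighted mean of the available sub-annual
#' samples; a pixel-year is flagged missing when the fraction of available
#' samples falls below `min_frac` (boundary inclusive). Annual input is
#' returned unchanged (idempotent).
#'
#' @param series A [gridded_series()] with monthly or 8-day cadence.
#' @param min_frac Minimum available fraction per pixel-year (default 0.5).
#' @return An annual [gridded_series()] on the grid's year axis.
#' @export
annual_mean <- function(series, min_frac = 0.5) {
  stopifnot(inherits(series, "gridded_series"))
  if (series$cadence == "annual") return(series)
  if (dim(series$values)[1] == 0L)
    stop("empty time axis", call. = FALSE)
  g <- series$grid
  nlat <- length(g$lat); nlon <- length(g$lon)
  out <- array(NA_real_, c(length(g$years), nlat, nlon))
  for (k in seq_along(g$years)) {
    idx <- which(series$time$year == g$years[k])
    if (length(idx) == 0L) next
    block <- series$values[idx, , , drop = FALSE]
    avail <- apply(!is.na(block), c(2, 3), sum)
    m <- apply(block, c(2, 3), function(v) mean(v, na.rm = TRUE))
    m[avail / length(idx) < min_frac] <- NA_real_
    m[avail == 0L] <- NA_real_
    out[k, , ] <- m
  }
  gridded_series(out, g, units = series$units, cadence = "annual",
                 name = series$name)
}

#' Divide a series by its mean
#'
#' Mean-normalisation makes trends read as fractional change per year and
#' makes every downstream comparison invariant to positive rescaling of the
#' raw units. A series whose mean is indistinguishable from zero (|mean| <
#' `tol_factor * max(|x|)`) has no defined normalisation; an all-`NA`
#' vector flagged with `attr(, "degenerate")` is returned.
#'
#' @param x Numeric vector (`NA` allowed and preserved).
#' @param tol_factor Zero-mean tolerance relative to `max(abs(x))`.
#' @return `x / mean(x)` (mean taken over available values), or the
#'   degenerate sentinel.
#' @examples
#' mean_normalise(c(2, 4, 6))
#' @export
mean_normalise <- function(x, tol_factor = 1e-12) {
  m <- mean(x, na.rm = TRUE)
  mx <- max(abs(x), na.rm = TRUE)
  if (!is.finite(m) || (mx > 0 && abs(m) < tol_factor * mx) ||
      (mx == 0 && m == 0))
    return(structure(rep(NA_real_, length(x)), degenerate = TRUE))
  x / m
}

#' Seawater density at atmospheric pressure (EOS-80)
#'
#' The Millero & Poisson (1981) one-atmosphere International Equation of
#' State: density as a polynomial in practical salinity and temperature.
#' Serves as the default equation of state for the mixed-layer-depth
#' criterion; any function with the same signature can replace it.
#'
#' @param salinity Practical salinity (PSU).
#' @param temperature In-situ temperature (degC).
#' @param pressure Ignored (surface form); kept for signature compatibility.
#' @return Density (kg m-3).
#' @export
eos_density <- function(salinity, temperature, pressure = 0) {
  t <- temperature; s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2
}

#' Mixed layer depth from a density criterion
#'
#' Computes the potential-density profile via the pluggable equation of
#' state and returns the shallowest depth at which density exceeds its
#' 10 m reference value by `criterion` (default 0.03 kg m-3), linearly
#' interpolated in density-depth between the bracketing levels. The
#' reference density itself is linearly interpolated to `ref_depth` when no
#' level sits exactly there. If the profile never exceeds the threshold the
#' deepest level is returned, flagged `attr(, "unresolved")`.
#'
#' @param temperature,salinity Profile values at `depths`.
#' @param depths Strictly increasing depths (m) reaching at least
#'   `ref_depth`.
#' @param criterion Density excess (kg m-3).
#' @param ref_depth Reference depth (m).
#' @param eos Equation of state `function(salinity, temperature, pressure)`;
#'   default [eos_density()]. Tests may pass a stub that returns a supplied
#'   density directly.
#' @return MLD in metres (possibly flagged `unresolved`).
#' @export
mld_from_profiles <- function(temperature, salinity, depths,
                              criterion = 0.03, ref_depth = 10,
                              eos = eos_density) {
  stopifnot(length(temperature) == length(depths),
            length(salinity) == length(depths))
  if (is.unsorted(depths, strictly = TRUE))
    stop("depths must be strictly increasing", call. = FALSE)
  if (max(depths) < ref_depth)
    stop("profile does not reach the reference depth", call. = FALSE)
  rho <- eos(salinity, temperature, depths)
  rho_ref <- stats::approx(depths, rho, xout = ref_depth, rule = 2)$y
  thresh <- rho_ref + criterion
  below <- which(rho > thresh & depths >= ref_depth)
  exact <- which(rho == thresh & depths >= ref_depth)
  if (length(exact) > 0 && (length(below) == 0 || exact[1] < below[1]))
    return(depths[exact[1]])
  if (length(below) == 0L)
    return(structure(depths[length(depths)], unresolved = TRUE))
  j <- below[1]
  if (j == 1L) return(depths[1])
  # linear interpolation in density between the bracketing levels
  depths[j - 1] + (thresh - rho[j - 1]) / (rho[j] - rho[j - 1]) *
    (depths[j] - depths[j - 1])
}
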