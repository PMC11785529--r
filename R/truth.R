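#' Ground-truth parameters for the synthetic gridded world
#'
#' A `truth_record` holds everything the synthetic generator needs and
#' everything a recovery test must know: the per-pixel regression structure
#' linking mean-normalised NPP to its mean-normalised drivers (SST, CHL,
#' MLD), the drivers' linear trends, the AR(1) interannual noise model, the
#' positive physical scales that map the dimensionless fields to physical
#' units, and the per-model coefficient shifts defining a pseudo-model
#' ensemble.
#'
#' On the mean-normalised scale each driver fluctuates around 1, so the
#' intercept defaults to `1 - beta_sst - beta_chl - beta_mld`, which makes
#' the noise-free NPP series have mean exactly 1 over the full time span and
#' keeps zero-noise coefficient recovery exact.
#'
#' @param grid A [grid_spec()].
#' @param beta_sst,beta_chl,beta_mld Per-pixel dimensionless coefficient
#'   matrices (`n_lat x n_lon`); scalars are recycled.
#' @param trend_sst,trend_chl,trend_mld Per-pixel driver trends, fraction of
#'   the mean per year; scalars recycled.
#' @param ar1_phi Lag-1 autocorrelation of the interannual noise, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation of the NPP residual noise
#'   on the mean-normalised scale (`>= 0`); zero gives an exact linear
#'   NPP-driver relation.
#' @param driver_noise_sd Innovation standard deviation of the drivers'
#'   interannual variability (default 0.05). Must be positive for the
#'   regression to be identifiable: with purely deterministic trends all
#'   three drivers are collinear in time.
#' @param seed Integer seed; regenerating with the same seed is bit-identical.
#' @param ensemble_shifts `n_models x 3` matrix (columns sst, chl, mld) of
#'   uniform location shifts added to the coefficient fields of each
#'   pseudo-model, or `NULL` for no ensemble.
#' @param delta_npp Prescribed end-of-century minus historical change in
#'   globally integrated NPP (Pg C per year) carried by each pseudo-model for
#'   the ranking read-out; length `n_models`.
#' @param intercept Per-pixel intercept matrix; defaults as described above.
#' @param scales Named list of positive physical scales for `npp`
#'   (mg C m-2 d-1), `sst` (degC), `chl` (mg m-3), `mld` (m); the scaling is
#'   multiplicative so downstream mean-normalisation cancels it exactly.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(grid,
                         beta_sst = 0, beta_chl = 0, beta_mld = 0,
                         trend_sst = 0, trend_chl = 0, trend_mld = 0,
                         ar1_phi = 0, noise_sd = 0, driver_noise_sd = 0.05,
                         seed = 1L,
                         ensemble_shifts = NULL, delta_npp = NULL,
                         intercept = NULL,
                         scales = list(npp = 500, sst = 18, chl = 0.3,
                                       mld = 80)) {
  stopifnot(inherits(grid, "grid_spec"))
  if (abs(ar1_phi) >= 1)
    stop("ar1_phi must satisfy |phi| < 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (driver_noise_sd < 0)
    stop("driver_noise_sd must be >= 0", call. = FALSE)
  as_field <- function(x) {
    if (length(x) == 1L)
      x <- matrix(x, length(grid$lat), length(grid$lon))
    stopifnot(nrow(x) == length(grid$lat), ncol(x) == length(grid$lon))
    x
  }
  beta_sst <- as_field(beta_sst); beta_chl <- as_field(beta_chl)
  beta_mld <- as_field(beta_mld)
  trend_sst <- as_field(trend_sst); trend_chl <- as_field(trend_chl)
  trend_mld <- as_field(trend_mld)
  if (is.null(intercept)) intercept <- 1 - beta_sst - beta_chl - beta_mld
  intercept <- as_field(intercept)
  if (!is.null(ensemble_shifts)) {
    ensemble_shifts <- as.matrix(ensemble_shifts)
    stopifnot(ncol(ensemble_shifts) == 3L)
    colnames(ensemble_shifts) <- c("sst", "chl", "mld")
    if (is.null(delta_npp)) delta_npp <- rep(0, nrow(ensemble_shifts))
    stopifnot(length(delta_npp) == nrow(ensemble_shifts))
  }
  stopifnot(all(unlist(scales) > 0))
  structure(list(grid = grid, intercept = intercept,
                 beta_sst = beta_sst, beta_chl = beta_chl,
                 beta_mld = beta_mld,
                 trend_sst = trend_sst, trend_chl = trend_chl,
                 trend_mld = trend_mld,
                 ar1_phi = ar1_phi, noise_sd = noise_sd,
                 driver_noise_sd = driver_noise_sd,
                 seed = as.integer(seed),
                 ensemble_shifts = ensemble_shifts, delta_npp = delta_npp,
                 scales = scales),
            class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> seed %d, ar1_phi %.2f, noise_sd %.3f, %s\n",
              x$seed, x$ar1_phi, x$noise_sd,
              if (is.null(x$ensemble_shifts)) "no ensemble"
              else paste(nrow(x$ensemble_shifts), "pseudo-models")))
  invisible(x)
}

#' Draw a realistic random truth record
#'
#' Generates smooth, latitudinally structured coefficient and trend fields
#' emulating the broad structure seen in observational driver analyses: SST
#' coefficients negative at low latitudes rising towards positive values
#' poleward, CHL coefficients uniformly positive and roughly half the SST
#' amplitude, MLD coefficients weakly negative (half again); driver trends of
#' a few tenths of a percent of the mean per year.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param ar1_phi,noise_sd,driver_noise_sd Noise model (see
#'   [truth_record()]).
#' @param n_models If `> 0`, draw this many pseudo-model shift triples with
#'   increasing magnitude and prescribed `delta_npp` values spanning declines
#'   to small increases.
#' @return A [truth_record()].
#' @export
random_truth <- function(grid, seed = 1L, ar1_phi = 0.3, noise_sd = 0.05,
                         driver_noise_sd = 0.05, n_models = 0L) {
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  latf <- matrix(abs(grid$lat) / 90, nlat, nlon)
  ripple <- function(amp) matrix(stats::rnorm(nlat * nlon, 0, amp), nlat, nlon)
  beta_sst <- -0.6 + 1.0 * latf + ripple(0.05)
  beta_chl <- 0.45 + 0.10 * (1 - latf) + ripple(0.04)
  beta_mld <- -0.20 + 0.10 * latf + ripple(0.03)
  trend_sst <- 0.0025 + ripple(5e-4)
  trend_chl <- -0.0030 + ripple(5e-4)
  trend_mld <- -0.0020 + ripple(5e-4)
  shifts <- NULL; dn <- NULL
  if (n_models > 0L) {
    base <- c(sst = 0.08, chl = 0.05, mld = 0.03)
    shifts <- outer(seq_len(n_models), base)
    colnames(shifts) <- names(base)
    dn <- seq(-3, 1, length.out = n_models)
  }
  truth_record(grid, beta_sst, beta_chl, beta_mld,
               trend_sst, trend_chl, trend_mld,
               ar1_phi = ar1_phi, noise_sd = noise_sd,
               driver_noise_sd = driver_noise_sd, seed = seed,
               ensemble_shifts = shifts, delta_npp = dn)
}
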