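# Stationary AR(1) noise cube (time, lat, lon): x_1 drawn from the
# stationary distribution so no burn-in is needed; sd is the innovation sd.
ar1_noise <- function(n_time, nlat, nlon, phi, sd) {
  if (sd == 0) return(array(0, c(n_time, nlat, nlon)))
  x <- array(0, c(n_time, nlat, nlon))
  x[1, , ] <- stats::rnorm(nlat * nlon, 0, sd / sqrt(1 - phi^2))
  if (n_time > 1L)
    for (t in 2:n_time)
      x[t, , ] <- phi * x[t - 1, , ] + stats::rnorm(nlat * nlon, 0, sd)
  x
}

# deterministic mean-normalised driver: 1 + trend * (t - mean(t)), so its
# mean over the full span is exactly 1
driver_deterministic <- function(trend_field, years) {
  tc <- years - mean(years)
  ar <- array(0, c(length(years), nrow(trend_field), ncol(trend_field)))
  for (t in seq_along(years))
    ar[t, , ] <- 1 + trend_field * tc[t]
  ar
}

# renormalise each pixel's series to unit sample mean over the record, so
# downstream mean-normalisation over the full span is an exact identity
unit_mean <- function(cube) {
  m <- apply(cube, c(2, 3), mean)
  sweep(cube, c(2, 3), m, "/")
}

#' Simulate a gridded NPP + driver dataset with known structure
#'
#' Each driver series is a per-pixel linear trend around a mean of one plus
#' stationary AR(1) interannual variability (`driver_noise_sd`),
#' renormalised to unit sample mean over the record; the NPP series is the
#' truth record's per-pixel linear combination of these unit-mean drivers
#' plus its own AR(1) residual noise (`noise_sd`). With `noise_sd = 0` the
#' NPP-driver relation is exactly linear and full-span mean-normalised
#' regression recovers the truth coefficients to machine precision. All fields are then multiplied by positive physical scales
#' (recorded in the truth record) so they arrive in plausible physical
#' units; because the scaling is purely multiplicative, downstream
#' mean-normalisation recovers the dimensionless structure exactly.
#'
#' @param grid A [grid_spec()]; must match the truth record's grid.
#' @param truth A [truth_record()].
#' @param seed Seed for this realisation; defaults to `truth$seed`. Distinct
#'   observation-like products are obtained by varying the seed while keeping
#'   the same truth.
#' @param missing_frac Fraction of NPP samples masked missing at random
#'   (default 0).
#' @return A list with annual [gridded_series()] `npp`, `sst`, `chl`, `mld`
#'   and the `truth` record.
#' @export
simulate_truth_dataset <- function(grid, truth, seed = truth$seed,
                                   missing_frac = 0) {
  stopifnot(inherits(grid, "grid_spec"), inherits(truth, "truth_record"))
  if (!identical(dim(truth$beta_sst),
                 c(length(grid$lat), length(grid$lon))))
    stop("grid and truth record shapes are inconsistent", call. = FALSE)
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  nt <- length(grid$years)
  phi <- truth$ar1_phi
  sd_drv <- truth$driver_noise_sd
  drv <- list(
    sst = unit_mean(driver_deterministic(truth$trend_sst, grid$years) +
                      ar1_noise(nt, nlat, nlon, phi, sd_drv)),
    chl = unit_mean(driver_deterministic(truth$trend_chl, grid$years) +
                      ar1_noise(nt, nlat, nlon, phi, sd_drv)),
    mld = unit_mean(driver_deterministic(truth$trend_mld, grid$years) +
                      ar1_noise(nt, nlat, nlon, phi, sd_drv)))
  npp <- ar1_noise(nt, nlat, nlon, phi, truth$noise_sd)
  for (t in seq_len(nt))
    npp[t, , ] <- npp[t, , ] + truth$intercept +
      truth$beta_sst * drv$sst[t, , ] +
      truth$beta_chl * drv$chl[t, , ] +
      truth$beta_mld * drv$mld[t, , ]
  if (missing_frac > 0) {
    drop <- stats::runif(length(npp)) < missing_frac
    npp[drop] <- NA_real_
  }
  land <- array(rep(grid$land_mask, each = nt), c(nt, nlat, nlon))
  apply_land <- function(a) { a[land] <- NA_real_; a }
  units <- c(npp = "mg C m-2 d-1", sst = "degC", chl = "mg m-3", mld = "m")
  out <- list(
    npp = gridded_series(apply_land(npp * truth$scales$npp), grid,
                         units[["npp"]], name = "npp"),
    sst = gridded_series(apply_land(drv$sst * truth$scales$sst), grid,
                         units[["sst"]], name = "sst"),
    chl = gridded_series(apply_land(drv$chl * truth$scales$chl), grid,
                         units[["chl"]], name = "chl"),
    mld = gridded_series(apply_land(drv$mld * truth$scales$mld), grid,
                         units[["mld"]], name = "mld"),
    truth = truth)
  out
}

#' Simulate a pseudo-model ensemble with shifted coefficient fields
#'
#' Model `k` is generated exactly like the observational truth except that
#' its coefficient fields are uniformly location-shifted by the truth
#' record's `ensemble_shifts[k, ]`, and it carries a prescribed `delta_npp`
#' scalar for the ranking read-out. Each model gets an independent noise
#' realisation derived deterministically from the base seed.
#'
#' @param grid A [grid_spec()].
#' @param truth A [truth_record()] with `ensemble_shifts` set.
#' @param n_models Number of models; must equal `nrow(ensemble_shifts)` and
#'   be at least 2 (Z-scores are undefined for fewer).
#' @return A list of model datasets (each as in [simulate_truth_dataset()],
#'   plus `delta_npp` and `model` id) and the shared `truth`.
#' @export
simulate_pseudo_ensemble <- function(grid, truth,
                                     n_models = nrow(truth$ensemble_shifts)) {
  stopifnot(inherits(truth, "truth_record"))
  if (is.null(truth$ensemble_shifts))
    stop("truth record carries no ensemble_shifts", call. = FALSE)
  if (is.null(n_models) || n_models < 2L)
    stop("need at least 2 models: Z-scores are undefined otherwise",
         call. = FALSE)
  if (n_models != nrow(truth$ensemble_shifts))
    stop("ensemble_shifts must have one row per model", call. = FALSE)
  models <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    sh <- truth$ensemble_shifts[k, ]
    tk <- truth_record(grid,
                       beta_sst = truth$beta_sst + sh[["sst"]],
                       beta_chl = truth$beta_chl + sh[["chl"]],
                       beta_mld = truth$beta_mld + sh[["mld"]],
                       trend_sst = truth$trend_sst,
                       trend_chl = truth$trend_chl,
                       trend_mld = truth$trend_mld,
                       ar1_phi = truth$ar1_phi, noise_sd = truth$noise_sd,
                       driver_noise_sd = truth$driver_noise_sd,
                       seed = truth$seed, scales = truth$scales)
    ds <- simulate_truth_dataset(grid, tk, seed = truth$seed + 1009L * k)
    ds$delta_npp <- truth$delta_npp[k]
    ds$model <- paste0("model_", k)
    models[[k]] <- ds
  }
  list(models = models, truth = truth)
}

#' Generate a single ocean-colour scene for the NPP algorithms
#'
#' Draws one snapshot of the fields the satellite NPP algorithms consume,
#' each log-uniform (or uniform) within documented plausible open-ocean
#' ranges: CHL 0.01-30 mg m-3, SST 0.5-30 degC (strictly positive by
#' contract; sub-zero polar temperatures are not represented), PAR 5-60
#' mol photon
#' m-2 d-1, bbp443 5e-4 to 1e-2 m-1, aph443 5e-3 to 1e-1 m-1, Kd490
#' 0.02-0.5 m-1, day length 6-18 h, MLD 10-300 m, nitracline 20-150 m;
#' the euphotic depth is derived from Kd490 as `4.6 / Kd490` (1% light
#' level), capped at 200 m.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param chl_range CHL bounds (mg m-3).
#' @return Named list of `n_lat x n_lon` matrices: `chl`, `sst`, `par`,
#'   `bbp443`, `aph443`, `kd490`, `zeu`, `day_length`, `mld`, `z_no3`.
#' @export
make_ocean_colour_scene <- function(grid, seed = 1L,
                                    chl_range = c(0.01, 30)) {
  stopifnot(inherits(grid, "grid_spec"))
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  runif_mat <- function(lo, hi)
    matrix(stats::runif(nlat * nlon, lo, hi), nlat, nlon)
  log_runif_mat <- function(lo, hi)
    exp(matrix(stats::runif(nlat * nlon, log(lo), log(hi)), nlat, nlon))
  kd490 <- log_runif_mat(0.02, 0.5)
  list(chl = log_runif_mat(chl_range[1], chl_range[2]),
       sst = runif_mat(0.5, 30),
       par = runif_mat(5, 60),
       bbp443 = log_runif_mat(5e-4, 1e-2),
       aph443 = log_runif_mat(5e-3, 1e-1),
       kd490 = kd490,
       zeu = pmin(4.6 / kd490, 200),
       day_length = runif_mat(6, 18),
       mld = log_runif_mat(10, 300),
       z_no3 = runif_mat(20, 150))
}
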