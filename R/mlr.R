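#' Newey-West rule-of-thumb truncation lag
#'
#' `lag = floor(4 * (T / 100)^(2/9))` for a series of length `T`: 2 for the
#' 26-year satellite record, 4 for a 165-year historical model run.
#'
#' @param T Series length in time steps (>= 1).
#' @return Integer lag.
#' @examples
#' newey_west_lag(26)
#' newey_west_lag(165)
#' @export
newey_west_lag <- function(T) {
  if (any(T < 1)) stop("series length must be >= 1", call. = FALSE)
  as.integer(floor(4 * (T / 100)^(2 / 9)))
}

#' Per-pixel multiple linear regression of NPP on its drivers
#'
#' Mean-normalises the four series, fits `npp ~ sst + chl + mld` by
#' ordinary least squares, and draws inference from the Newey-West
#' heteroskedasticity-and-autocorrelation-consistent covariance at the
#' rule-of-thumb lag (Bartlett kernel, small-sample degrees-of-freedom
#' adjustment, t reference distribution with `n - 4` degrees of freedom).
#' The overall-model test is a HAC Wald F-test of the three slopes.
#'
#' No fit is attempted (a skip sentinel is returned) if any series has a
#' missing year, or if any driver's variance on the mean-normalised scale
#' is at or below `var_tol`. A perfect fit (residual variance numerically
#' zero, as for noise-free synthetic data) returns exact coefficients with
#' p-values of zero and `perfect_fit = TRUE`: the inference is degenerate
#' but the cell is retained.
#'
#' @param npp,sst,chl,mld Equal-length annual series in raw units; they are
#'   mean-normalised internally, so any positive rescaling of an input
#'   leaves the coefficients unchanged.
#' @param var_tol Variance threshold for the "essentially constant driver"
#'   skip rule, on the mean-normalised scale.
#' @return An object of class `driver_mlr` with elements `coefficients`
#'   (named: sst, chl, mld), `intercept`, `std_errors` (HAC), `p_values`,
#'   `adjusted_r2`,
#'   `model_p`, `n`, `hac_lag`, `perfect_fit` — or the skip sentinel, a
#'   `driver_mlr_skip` object carrying the `reason`.
#' @export
fit_pixel_mlr <- function(npp, sst, chl, mld, var_tol = 1e-10) {
  n <- length(npp)
  stopifnot(length(sst) == n, length(chl) == n, length(mld) == n)
  skip <- function(reason)
    structure(list(reason = reason), class = "driver_mlr_skip")
  if (anyNA(npp) || anyNA(sst) || anyNA(chl) || anyNA(mld))
    return(skip("missing year"))
  if (n < 6L) return(skip("series too short"))
  mats <- lapply(list(npp = npp, sst = sst, chl = chl, mld = mld),
                 mean_normalise)
  if (any(vapply(mats, function(v) isTRUE(attr(v, "degenerate")), TRUE)))
    return(skip("zero-mean series"))
  drv_var <- vapply(mats[c("sst", "chl", "mld")], stats::var, numeric(1))
  if (any(drv_var <= var_tol)) return(skip("driver variance ~0"))
  df <- as.data.frame(mats)
  fit <- stats::lm(npp ~ sst + chl + mld, data = df)
  beta <- stats::coef(fit)
  if (anyNA(beta)) return(skip("collinear drivers"))
  lag <- newey_west_lag(n)
  sigma2 <- sum(stats::resid(fit)^2) / (n - 4L)
  if (sigma2 < 1e-16 * stats::var(df$npp) || sigma2 == 0) {
    return(structure(list(
      coefficients = beta[c("sst", "chl", "mld")],
      intercept = unname(beta[1]),
      std_errors = stats::setNames(c(0, 0, 0), c("sst", "chl", "mld")),
      p_values = stats::setNames(c(0, 0, 0), c("sst", "chl", "mld")),
      adjusted_r2 = 1, model_p = 0, n = n, hac_lag = lag,
      perfect_fit = TRUE), class = "driver_mlr"))
  }
  V <- sandwich::NeweyWest(fit, lag = lag, prewhite = FALSE, adjust = TRUE)
  se <- sqrt(diag(V))
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df = n - 4L)
  # HAC Wald test that all three slopes vanish
  b3 <- beta[c("sst", "chl", "mld")]
  V3 <- V[c("sst", "chl", "mld"), c("sst", "chl", "mld")]
  wald <- tryCatch(drop(t(b3) %*% solve(V3, b3)) / 3,
                   error = function(e) NA_real_)
  model_p <- if (is.na(wald)) NA_real_ else
    stats::pf(wald, 3, n - 4L, lower.tail = FALSE)
  structure(list(
    coefficients = b3, intercept = unname(beta[1]),
    std_errors = se[c("sst", "chl", "mld")],
    p_values = p[c("sst", "chl", "mld")],
    adjusted_r2 = summary(fit)$adj.r.squared,
    model_p = model_p, n = n, hac_lag = lag, perfect_fit = FALSE),
    class = "driver_mlr")
}

#' @export
print.driver_mlr <- function(x, ...) {
  cat(sprintf(
    "<driver_mlr> n=%d lag=%d adjR2=%.3f modelP=%.3g%s\n",
    x$n, x$hac_lag, x$adjusted_r2, x$model_p,
    if (x$perfect_fit) " (perfect fit)" else ""))
  print(round(rbind(coef = x$coefficients, p = x$p_values), 4))
  invisible(x)
}

#' @export
print.driver_mlr_skip <- function(x, ...) {
  cat("<driver_mlr_skip>", x$reason, "\n")
  invisible(x)
}

#' Gridded MLR coefficient maps for one jackknife assessment
#'
#' Fits [fit_pixel_mlr()] at every ocean cell over the assessment's
#' retained years and masks coefficients by the significance rule: a
#' driver's coefficient is kept where its own HAC t-test p-value is at most
#' `alpha` and (optionally) the overall model test passes at `alpha`.
#'
#' @param dataset A list with annual [gridded_series()] `npp`, `sst`,
#'   `chl`, `mld` on one grid (as from [simulate_truth_dataset()]).
#' @param assessment One row of [jackknife_windows()] (list/data.frame with
#'   `start`, `end`), or `NULL` for the full span.
#' @param alpha Significance level (default 0.05).
#' @param var_tol Passed to [fit_pixel_mlr()].
#' @param require_model_sig Also require the overall model test (default
#'   `TRUE`, the strict reading).
#' @param require_coef_sig Require the per-coefficient test (default
#'   `TRUE`).
#' @return A `coefficient_maps` object: per-driver `coef` and `p` matrices,
#'   logical `significant` masks, `adjusted_r2` and `model_p` matrices, and
#'   per-cell skip `reason` matrix.
#' @export
mlr_coefficient_maps <- function(dataset, assessment = NULL, alpha = 0.05,
                                 var_tol = 1e-10,
                                 require_model_sig = TRUE,
                                 require_coef_sig = TRUE) {
  g <- dataset$npp$grid
  nlat <- length(g$lat); nlon <- length(g$lon)
  if (nlat == 0L || nlon == 0L) stop("empty grid", call. = FALSE)
  idx <- if (is.null(assessment)) seq_along(g$years) else
    seq(assessment$start, assessment$end)
  drivers <- c("sst", "chl", "mld")
  coefs <- pvals <- lapply(drivers, function(d)
    matrix(NA_real_, nlat, nlon))
  names(coefs) <- names(pvals) <- drivers
  sig <- lapply(coefs, function(m) matrix(FALSE, nlat, nlon))
  r2 <- mp <- matrix(NA_real_, nlat, nlon)
  reason <- matrix(NA_character_, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    if (g$land_mask[i, j]) { reason[i, j] <- "land"; next }
    f <- fit_pixel_mlr(dataset$npp$values[idx, i, j],
                       dataset$sst$values[idx, i, j],
                       dataset$chl$values[idx, i, j],
                       dataset$mld$values[idx, i, j], var_tol = var_tol)
    if (inherits(f, "driver_mlr_skip")) { reason[i, j] <- f$reason; next }
    r2[i, j] <- f$adjusted_r2; mp[i, j] <- f$model_p
    model_ok <- !require_model_sig ||
      (!is.na(f$model_p) && f$model_p <= alpha)
    for (d in drivers) {
      coefs[[d]][i, j] <- f$coefficients[[d]]
      pvals[[d]][i, j] <- f$p_values[[d]]
      coef_ok <- !require_coef_sig || f$p_values[[d]] <= alpha
      sig[[d]][i, j] <- model_ok && coef_ok
    }
  }
  structure(list(coef = coefs, p = pvals, significant = sig,
                 adjusted_r2 = r2, model_p = mp, reason = reason,
                 grid = g, years = g$years[idx], alpha = alpha),
            class = "coefficient_maps")
}

#' @export
print.coefficient_maps <- function(x, ...) {
  nsig <- vapply(x$significant, sum, integer(1))
  nfit <- sum(!is.na(x$adjusted_r2))
  cat(sprintf("<coefficient_maps> years %d-%d, %d cells fitted; significant: %s\n",
              min(x$years), max(x$years), nfit,
              paste(names(nsig), nsig, sep = "=", collapse = " ")))
  invisible(x)
}

#' Zonal means and standard deviations of significant coefficients
#'
#' Summarises a [mlr_coefficient_maps()] result per latitude row using only
#' cells whose regression passed the significance rule.
#'
#' @param maps A `coefficient_maps` object.
#' @return Data frame with `lat`, `driver`, `mean`, `sd`, `n_cells`.
#' @export
zonal_summary <- function(maps) {
  stopifnot(inherits(maps, "coefficient_maps"))
  g <- maps$grid
  out <- do.call(rbind, lapply(names(maps$coef), function(d) {
    do.call(rbind, lapply(seq_along(g$lat), function(i) {
      vals <- maps$coef[[d]][i, ][maps$significant[[d]][i, ]]
      data.frame(lat = g$lat[i], driver = d,
                 mean = if (length(vals)) mean(vals) else NA_real_,
                 sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
                 n_cells = length(vals))
    }))
  }))
  rownames(out) <- NULL
  out
}
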