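#' Enumerate jackknife assessments of a time series
#'
#' All contiguous windows of `window` years obtainable by trimming only the
#' start and/or end of an `n_years` series: exactly
#' `n_years - window + 1` assessments. Retaining 20 of 26 years therefore
#' yields 7 assessments.
#'
#' @param n_years Series length in years.
#' @param window Retained window length, `0 < window <= n_years`.
#' @return Data frame with columns `index`, `start`, `end` (1-based,
#'   inclusive positions on the year axis).
#' @examples
#' jackknife_windows(26, 20)
#' @export
jackknife_windows <- function(n_years, window) {
  if (window < 1L || window > n_years)
    stop("window must satisfy 0 < window <= n_years", call. = FALSE)
  k <- n_years - window + 1L
  data.frame(index = seq_len(k), start = seq_len(k),
             end = seq_len(k) + window - 1L)
}

#' Mann-Kendall trend test with Theil-Sen slope
#'
#' The S statistic over all pairs, tie-corrected variance, continuity
#' correction and two-sided normal p-value; the accompanying slope is the
#' Theil-Sen median of pairwise slopes. The p-value depends on the data only
#' through the ordering of values, so it is invariant under strictly
#' monotone transforms.
#'
#' @param y Values; `NA` dropped together with the matching times.
#' @param t Times (defaults to `seq_along(y)`).
#' @return List with `s`, `var_s`, `z`, `p_value`, `slope`.
#' @export
mann_kendall <- function(y, t = seq_along(y)) {
  keep <- !is.na(y)
  y <- y[keep]; t <- t[keep]
  n <- length(y)
  if (n < 3L) stop("Mann-Kendall needs at least 3 points", call. = FALSE)
  s <- 0
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    d <- y[(i + 1):n] - y[i]
    s <- s + sum(sign(d))
    slopes <- c(slopes, d / (t[(i + 1):n] - t[i]))
  }
  ties <- table(y)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s == 0) 0 else (s - sign(s)) / sqrt(var_s)
  list(s = s, var_s = var_s, z = z,
       p_value = if (var_s == 0) 1 else 2 * stats::pnorm(-abs(z)),
       slope = stats::median(slopes))
}

#' Per-pixel trend with a normality-gated method switch
#'
#' The trend protocol applied to one annual series: (1) exclude the pixel
#' if less than `min_frac` of the series is available; (2) test the series
#' values for normality with the D'Agostino-Pearson omnibus test; (3) if
#' normality is not rejected at `alpha`, fit a Huber robust regression of
#' value on year (tuning constant `huber_eps`, the 95%-efficiency value
#' 1.35), treating points whose final Huber weight is below one as removed
#' outliers — if fewer than `min_frac` of the points survive, no trend is
#' reported; (4) if normality is rejected, use the Mann-Kendall test with
#' the Theil-Sen slope. Series too short for the normality test (< 8
#' points) take the Huber path, as normality cannot be rejected.
#'
#' @param y Annual values (`NA` = missing).
#' @param years Matching year axis (default `seq_along(y)`).
#' @param min_frac Minimum available fraction (default 0.5, boundary
#'   inclusive).
#' @param alpha Normality-test significance level.
#' @param huber_eps Huber tuning constant.
#' @return A `trend_result` list: `slope` (units per year), `p_value`,
#'   `method` (`"huber"`, `"mann_kendall"` or `"none"`), `normality_p`,
#'   `n_used`.
#' @export
pixel_trend <- function(y, years = seq_along(y), min_frac = 0.5,
                        alpha = 0.05, huber_eps = 1.35) {
  stopifnot(length(y) == length(years))
  n_total <- length(y)
  keep <- !is.na(y)
  none <- function(normality_p = NA_real_)
    structure(list(slope = NA_real_, p_value = NA_real_, method = "none",
                   normality_p = normality_p, n_used = 0L),
              class = "trend_result")
  if (n_total == 0L || sum(keep) / n_total < min_frac) return(none())
  yy <- y[keep]; tt <- years[keep]
  if (stats::sd(yy) == 0)
    return(structure(list(slope = 0, p_value = 1, method = "huber",
                          normality_p = 1, n_used = length(yy)),
                     class = "trend_result"))
  norm_p <- if (length(yy) >= 8L) dagostino_pearson(yy)$p_value else 1
  if (norm_p > alpha) {
    fit <- MASS::rlm(yy ~ tt, psi = MASS::psi.huber, k = huber_eps,
                     maxit = 100)
    w <- fit$w
    n_kept <- sum(w >= 1 - 1e-8)      # down-weighted points count as removed
    if (n_kept / n_total < min_frac) return(none(norm_p))
    sm <- summary(fit)
    tval <- sm$coefficients["tt", "t value"]
    p <- 2 * stats::pt(-abs(tval), df = length(yy) - 2)
    structure(list(slope = unname(stats::coef(fit)["tt"]), p_value = p,
                   method = "huber", normality_p = norm_p,
                   n_used = length(yy)),
              class = "trend_result")
  } else {
    mk <- mann_kendall(yy, tt)
    structure(list(slope = mk$slope, p_value = mk$p_value,
                   method = "mann_kendall", normality_p = norm_p,
                   n_used = length(yy)),
              class = "trend_result")
  }
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> method=%s slope=%.4g p=%.3g (n=%d)\n",
              x$method, x$slope, x$p_value, x$n_used))
  invisible(x)
}

#' Per-pixel trend maps for a gridded annual series
#'
#' Applies [pixel_trend()] at every ocean cell.
#'
#' @param series An annual [gridded_series()].
#' @inheritParams pixel_trend
#' @return List of matrices `slope`, `p_value`, `normality_p` and a
#'   character matrix `method`.
#' @export
trend_map <- function(series, min_frac = 0.5, alpha = 0.05,
                      huber_eps = 1.35) {
  stopifnot(inherits(series, "gridded_series"))
  g <- series$grid
  nlat <- length(g$lat); nlon <- length(g$lon)
  slope <- p <- np <- matrix(NA_real_, nlat, nlon)
  method <- matrix("none", nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    if (g$land_mask[i, j]) next
    tr <- pixel_trend(series$values[, i, j], g$years, min_frac, alpha,
                      huber_eps)
    slope[i, j] <- tr$slope; p[i, j] <- tr$p_value
    np[i, j] <- tr$normality_p; method[i, j] <- tr$method
  }
  list(slope = slope, p_value = p, normality_p = np, method = method)
}

#' Area-weighted regional trend in percent per year
#'
#' Builds the area-weighted spatial mean series, mean-normalises it and
#' returns the ordinary-least-squares slope times 100 (% per year). Years
#' with no spatial coverage are dropped (with a message); weights are
#' renormalised over the cells available each year.
#'
#' @param series An annual [gridded_series()].
#' @param weights [area_weights()] for the grid (default computed).
#' @return Slope in percent per year.
#' @export
regional_trend <- function(series, weights = area_weights(series$grid)) {
  stopifnot(inherits(series, "gridded_series"))
  g <- series$grid
  nt <- dim(series$values)[1]
  sm <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    v <- series$values[t, , ]
    ok <- !is.na(v) & weights > 0
    if (!any(ok)) next
    sm[t] <- sum(v[ok] * weights[ok]) / sum(weights[ok])
  }
  keep <- !is.na(sm)
  if (sum(keep) < 2L) stop("fewer than 2 years with data", call. = FALSE)
  if (any(!keep))
    message("regional_trend: dropped ", sum(!keep),
            " year(s) with zero spatial coverage")
  yrs <- g$years[keep]
  norm <- mean_normalise(sm[keep])
  if (isTRUE(attr(norm, "degenerate")))
    stop("spatial mean series has zero mean; trend undefined",
         call. = FALSE)
  unname(stats::coef(stats::lm(norm ~ yrs))[2]) * 100
}

#' Change in globally integrated NPP between two reference windows
#'
#' Area-weighted global mean NPP (mol C m-2 d-1) is averaged over a
#' historical window and a future window; the difference is integrated over
#' the ocean area and converted to Pg C per year using 12.011 g C per mol, a
#' 365-day year and 1 Pg = 1e15 g (all configurable).
#'
#' @param hist,future Annual [gridded_series()] of NPP in mol C m-2 d-1.
#' @param weights [area_weights()] shared by both grids.
#' @param ocean_area Ocean area in m^2.
#' @param hist_window,future_window Year ranges `c(first, last)` that must
#'   be present in the respective series.
#' @param g_per_mol,days_per_year,g_per_pg Unit constants.
#' @return Delta NPP in Pg C per year.
#' @export
delta_npp <- function(hist, future, weights = area_weights(hist$grid),
                      ocean_area = 3.619e14,
                      hist_window = range(hist$grid$years),
                      future_window = range(future$grid$years),
                      g_per_mol = 12.011, days_per_year = 365,
                      g_per_pg = 1e15) {
  window_mean <- function(series, win) {
    idx <- which(series$grid$years >= win[1] & series$grid$years <= win[2])
    if (length(idx) == 0L)
      stop("reference window absent from series", call. = FALSE)
    vals <- vapply(idx, function(t) {
      v <- series$values[t, , ]
      ok <- !is.na(v) & weights > 0
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * weights[ok]) / sum(weights[ok])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  diff_flux <- window_mean(future, future_window) -
    window_mean(hist, hist_window)                     # mol C m-2 d-1
  diff_flux * ocean_area * g_per_mol * days_per_year / g_per_pg
}
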