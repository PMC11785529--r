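# shared fixtures and independent oracles

test_grid <- function(nlat = 8, nlon = 10, years = 1998:2023,
                      land = NULL) {
  grid_spec(seq(-60, 60, length.out = nlat),
            seq(-170, 170, length.out = nlon), years, land)
}

# brute-force first-Wasserstein oracle: piecewise integration of |U - V|
# between consecutive breakpoints, via stats::ecdf evaluated at segment
# midpoints (the ECDFs are constant on each open segment)
emd_oracle <- function(u, v) {
  fu <- stats::ecdf(u); fv <- stats::ecdf(v)
  br <- sort(unique(c(u, v)))
  if (length(br) < 2) return(0)
  mid <- (br[-1] + br[-length(br)]) / 2
  sum(abs(fu(mid) - fv(mid)) * diff(br))
}

# AR(1) series starting from the stationary distribution
ar1_series <- function(n, phi, sd = 0.05) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, sd)
  x
}

# one-cell ocean-colour inputs with benign defaults
scene_point <- function(...) {
  base <- list(chl = 0.5, sst = 15, par = 30, day_length = 12, zeu = 50,
               bbp443 = 2e-3, aph443 = 0.02, kd490 = 0.1, mld = 40,
               z_no3 = 80)
  utils::modifyList(base, list(...))
}
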