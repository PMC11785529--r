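test_that("the rule-of-thumb lag floors correctly at reference lengths", {
  expect_equal(newey_west_lag(100), 4L)
  expect_equal(newey_west_lag(26), 2L)
  expect_equal(newey_west_lag(165), 4L)
  expect_equal(newey_west_lag(1), 1L)
  expect_error(newey_west_lag(0), ">= 1")
})

test_that("exact linear relations are recovered to machine precision", {
  set.seed(21)
  n <- 26
  sst <- 1 + ar1_series(n, 0.3)
  chl <- 1 + ar1_series(n, 0.3)
  mld <- 1 + ar1_series(n, 0.3)
  npp <- 1 + 0.5 * (sst / mean(sst) - 1)
  f <- fit_pixel_mlr(npp, sst, chl, mld)
  expect_s3_class(f, "driver_mlr")
  expect_true(f$perfect_fit)
  expect_equal(unname(f$coefficients),
               c(0.5 * 1 / mean(npp), 0, 0), tolerance = 1e-8)
  expect_equal(unname(f$p_values), c(0, 0, 0))
})

test_that("degenerate inputs return skip sentinels", {
  set.seed(22)
  x <- 1 + ar1_series(26, 0.3)
  y <- 1 + ar1_series(26, 0.3)
  expect_s3_class(fit_pixel_mlr(y, x, rep(1, 26), x + rnorm(26, 0, 0.01)),
                  "driver_mlr_skip")          # constant driver
  ym <- y; ym[5] <- NA
  expect_s3_class(fit_pixel_mlr(ym, x, x + rnorm(26, 0, 0.01),
                                x + rnorm(26, 0, 0.01)),
                  "driver_mlr_skip")          # missing year
  t <- 1:26
  expect_s3_class(fit_pixel_mlr(y, 1 + 0.01 * t, 1 + 0.02 * t,
                                1 - 0.01 * t),
                  "driver_mlr_skip")          # collinear drivers
})

test_that("coefficients are invariant to positive rescaling of raw inputs", {
  set.seed(23)
  n <- 26
  sst <- 15 * (1 + ar1_series(n, 0.3))
  chl <- 0.3 * (1 + ar1_series(n, 0.3))
  mld <- 80 * (1 + ar1_series(n, 0.3))
  npp <- 500 * (1 + 0.4 * ar1_series(n, 0.3) + rnorm(n, 0, 0.01))
  f0 <- fit_pixel_mlr(npp, sst, chl, mld)
  for (alpha in c(0.001, 12, 4000)) {
    f1 <- fit_pixel_mlr(npp * alpha, sst, chl, mld)
    f2 <- fit_pixel_mlr(npp, sst * alpha, chl, mld)
    expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-10)
    expect_equal(f2$coefficients, f0$coefficients, tolerance = 1e-10)
    expect_equal(f1$p_values, f0$p_values, tolerance = 1e-8)
  }
})

test_that("HAC standard errors exceed classical ones under autocorrelation", {
  # at the historical model-record length the kernel estimator is past its
  # small-sample downward bias and the expected ordering holds
  set.seed(24)
  n <- 165; reps <- 200
  ratio <- numeric(reps)
  for (r in seq_len(reps)) {
    sst <- 1 + ar1_series(n, 0.5)
    chl <- 1 + ar1_series(n, 0.5)
    mld <- 1 + ar1_series(n, 0.5)
    npp <- 1 + 0.3 * (sst - 1) + ar1_series(n, 0.5, 0.03)
    f <- fit_pixel_mlr(npp, sst, chl, mld)
    if (inherits(f, "driver_mlr_skip")) next
    ols <- lm(npp / mean(npp) ~ I(sst / mean(sst)) + I(chl / mean(chl)) +
                I(mld / mean(mld)))
    ratio[r] <- f$std_errors[["sst"]] /
      summary(ols)$coefficients[2, "Std. Error"]
  }
  expect_gt(mean(ratio[ratio > 0]), 1)
})

test_that("coefficient estimates are unbiased within Monte Carlo error", {
  set.seed(25)
  n <- 26; reps <- 500
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    sst <- 1 + ar1_series(n, 0.3)
    chl <- 1 + ar1_series(n, 0.3)
    mld <- 1 + ar1_series(n, 0.3)
    npp <- 1 + 0.5 * (sst / mean(sst) - 1) + ar1_series(n, 0.3, 0.02)
    f <- fit_pixel_mlr(npp, sst, chl, mld)
    est[r] <- if (inherits(f, "driver_mlr_skip")) NA else
      f$coefficients[["sst"]]
  }
  est <- est[!is.na(est)]
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 2 * mcse + 0.01)
})

test_that("coefficient maps recover a noiseless truth and mask degenerate cells", {
  g <- test_grid(5, 6)
  tr <- random_truth(g, seed = 31, noise_sd = 0)
  ds <- simulate_truth_dataset(g, tr)
  maps <- mlr_coefficient_maps(ds)
  for (d in c("sst", "chl", "mld")) {
    err <- abs(maps$coef[[d]] - tr[[paste0("beta_", d)]])
    expect_lt(max(err), 1e-8)
    expect_true(all(maps$significant[[d]]))
  }
  # constant drivers: everything skipped, no crash, fully masked
  flat <- ds
  for (v in c("sst", "chl", "mld"))
    flat[[v]]$values[] <- 1
  m2 <- mlr_coefficient_maps(flat)
  expect_true(all(!m2$significant$sst))
  expect_true(all(is.na(m2$coef$sst)))
  expect_true(all(m2$reason[!g$land_mask] == "driver variance ~0"))
})

test_that("zonal summaries are near a zonally constant truth under noise", {
  g <- test_grid(4, 14)
  tr <- truth_record(g, beta_sst = 0.6, beta_chl = 0.4, beta_mld = -0.3,
                     ar1_phi = 0, noise_sd = 0.01, driver_noise_sd = 0.05,
                     seed = 33)
  ds <- simulate_truth_dataset(g, tr)
  zs <- zonal_summary(mlr_coefficient_maps(ds))
  sstrows <- zs[zs$driver == "sst" & zs$n_cells > 3, ]
  expect_gt(nrow(sstrows), 0)
  # zonal mean within 3 standard errors of the constant truth per band
  for (k in seq_len(nrow(sstrows))) {
    se <- sstrows$sd[k] / sqrt(sstrows$n_cells[k])
    expect_lt(abs(sstrows$mean[k] - 0.6), 3 * se + 0.02)
  }
})
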