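test_that("jackknife enumeration trims only start and end years", {
  w <- jackknife_windows(26, 20)
  expect_equal(nrow(w), 7)
  expect_equal(w$end - w$start + 1L, rep(20L, 7))
  expect_false(any(duplicated(w[, c("start", "end")])))
  expect_equal(nrow(jackknife_windows(5, 5)), 1)
  expect_equal(nrow(jackknife_windows(10, 8)), 3)
  expect_error(jackknife_windows(10, 11), "window")
  # count law K = n - w + 1 across random valid cases
  set.seed(1)
  for (r in 1:25) {
    n <- sample(2:60, 1); wlen <- sample(seq_len(n), 1)
    expect_equal(nrow(jackknife_windows(n, wlen)), n - wlen + 1L)
  }
})

test_that("Mann-Kendall matches its exact S statistic and the Kendall test", {
  # fully concordant series: S = n(n-1)/2
  y <- exp(0.3 * (1:26))
  mk <- mann_kendall(y)
  expect_equal(mk$s, 26 * 25 / 2)
  expect_gt(mk$slope, 0)
  expect_lt(mk$p_value, 0.01)
  # independent route: cor.test's Kendall tau z-statistic on random series
  set.seed(7)
  for (r in 1:20) {
    yr <- rnorm(15 + r)
    mk <- mann_kendall(yr)
    ct <- suppressWarnings(stats::cor.test(yr, seq_along(yr),
                                           method = "kendall",
                                           exact = FALSE,
                                           continuity = TRUE))
    expect_equal(mk$p_value, unname(ct$p.value), tolerance = 1e-10)
  }
  # p invariant under strictly monotone transforms of the values
  set.seed(8)
  y <- cumsum(rnorm(20)) + 3
  expect_equal(mann_kendall(exp(y))$p_value, mann_kendall(y)$p_value)
  expect_equal(mann_kendall(y^3)$p_value, mann_kendall(y)$p_value)
})

test_that("the trend gate routes by normality and honours coverage", {
  y <- c(rep(NA, 14), rnorm(12))                 # > 50% missing
  expect_equal(pixel_trend(y)$method, "none")
  set.seed(3)
  tr <- pixel_trend(3 * (1:26) + rnorm(26))
  expect_equal(tr$method, "huber")
  expect_gt(tr$slope, 2.5); expect_lt(tr$slope, 3.5)
  tr2 <- pixel_trend(exp(0.3 * (1:26)))
  expect_equal(tr2$method, "mann_kendall")
  expect_gt(tr2$slope, 0)
  expect_lt(tr2$p_value, 0.01)
  # constant series: zero slope, p = 1
  trc <- pixel_trend(rep(2, 26))
  expect_equal(trc$slope, 0); expect_equal(trc$p_value, 1)
})

test_that("Huber equals OLS exactly on noise-free lines", {
  y <- 0.7 * (1:26) - 3
  tr <- pixel_trend(y)
  expect_equal(tr$method, "huber")
  expect_equal(tr$slope, 0.7, tolerance = 1e-10)
  set.seed(5)
  for (r in 1:10) {
    a <- rnorm(1); b <- rnorm(1)
    yy <- a + b * (1:20)
    ols <- unname(coef(lm(yy ~ I(1:20)))[2])
    expect_equal(pixel_trend(yy)$slope, ols, tolerance = 1e-9)
  }
})

test_that("trend slope CIs attain nominal coverage on AR(0) Gaussian fields", {
  set.seed(17)
  n <- 26; reps <- 500; hits <- 0; slopes <- numeric(reps)
  for (r in seq_len(reps)) {
    y <- 1 + 0.05 * (1:n) + rnorm(n, 0, 0.3)
    fit <- MASS::rlm(y ~ I(1:n), psi = MASS::psi.huber, k = 1.35)
    sm <- summary(fit)$coefficients
    ci <- sm[2, 1] + c(-1, 1) * qt(0.975, n - 2) * sm[2, 2]
    hits <- hits + (ci[1] <= 0.05 && 0.05 <= ci[2])
    slopes[r] <- pixel_trend(y)$slope
  }
  expect_gte(hits / reps, 0.90)
  expect_lte(hits / reps, 0.99)
  expect_lt(abs(mean(slopes) - 0.05), 0.01)
})

test_that("regional trends are mean-normalised, weighted and scale invariant", {
  g <- test_grid(3, 4, years = 2000:2002)
  vals <- array(rep(c(1, 2, 3), each = 1), c(3, 3, 4))
  s <- gridded_series(vals, g, name = "npp")
  expect_equal(regional_trend(s), 50, tolerance = 1e-10)
  sc <- gridded_series(array(2, c(3, 3, 4)), g)
  expect_equal(regional_trend(sc), 0, tolerance = 1e-12)
  s2 <- gridded_series(vals * 37.5, g)
  expect_equal(regional_trend(s2), regional_trend(s), tolerance = 1e-10)
})

test_that("delta NPP converts window means to Pg C per year", {
  g <- test_grid(2, 2, years = 1995:2014)
  gf <- grid_spec(g$lat, g$lon, 2081:2100)
  h <- gridded_series(array(2, c(20, 2, 2)), g, units = "mol C m-2 d-1")
  f0 <- gridded_series(array(2, c(20, 2, 2)), gf, units = "mol C m-2 d-1")
  expect_equal(delta_npp(h, f0), 0)
  # uniform drop of 1 mol C m-2 d-1 over 1 m^2 of ocean
  f1 <- gridded_series(array(1, c(20, 2, 2)), gf, units = "mol C m-2 d-1")
  expect_equal(delta_npp(h, f1, ocean_area = 1),
               -12.011 * 365 / 1e15)
  expect_lt(delta_npp(h, f1), 0)
  expect_error(delta_npp(h, f1, future_window = c(2200, 2220)), "window")
})
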