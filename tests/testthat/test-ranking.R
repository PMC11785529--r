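test_that("the IQR fence removes only extreme outliers", {
  expect_equal(iqr_fence(c(1:8, 1000)), 1:8)       # fence [-9, 19]
  expect_equal(iqr_fence(rep(4, 6)), rep(4, 6))    # degenerate IQR
  x <- c(2, 3, 4, 5, 6)
  expect_equal(iqr_fence(x), x)                    # all inside
  short <- iqr_fence(c(1, 2, 50))
  expect_equal(as.numeric(short), c(1, 2, 50))     # too few: unfiltered
  expect_true(isTRUE(attr(short, "unfiltered")))
})

test_that("the 1-D Wasserstein distance matches brute-force CDF integration", {
  expect_equal(emd_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd_1d(0, 1), 1)
  expect_equal(emd_1d(1:4, 2:5), 1)
  expect_error(emd_1d(numeric(0), 1), "non-empty")
  set.seed(41)
  for (r in 1:60) {
    u <- rnorm(sample(2:25, 1), sd = runif(1, 0.1, 5))
    v <- rnorm(sample(2:25, 1), mean = runif(1, -2, 2))
    expect_equal(emd_1d(u, v), emd_oracle(u, v), tolerance = 1e-12)
    expect_equal(emd_1d(u, v), emd_1d(v, u))           # symmetry
    delta <- runif(1, -3, 3)
    expect_equal(emd_1d(u, u + delta), abs(delta), tolerance = 1e-10)
  }
})

test_that("EMD is scale equivariant and rankings scale invariant", {
  set.seed(42)
  u <- rnorm(30); v <- rnorm(25, 1)
  for (alpha in c(0.2, 7)) {
    expect_equal(emd_1d(alpha * u, alpha * v), alpha * emd_1d(u, v),
                 tolerance = 1e-12)
  }
  tab <- data.frame(model = rep(c("a", "b", "c"), each = 3),
                    driver = rep(c("sst", "chl", "mld"), 3),
                    emd = c(1, 2, 3, 2, 3, 4, 5, 5, 5))
  r1 <- rank_models(tab)
  tab2 <- tab; tab2$emd <- tab2$emd * 11
  r2 <- rank_models(tab2)
  expect_equal(r2$model, r1$model)
  expect_equal(r2$rank, r1$rank)
})

test_that("Z-scores use the sample deviation with a degenerate convention", {
  expect_equal(zscore(4, c(2, 4, 6)), 0)
  expect_equal(zscore(6, c(2, 4, 6)), 1)            # sample sd = 2
  expect_equal(zscore(10, c(5, 5, 5)), 0)           # degenerate ensemble
  expect_error(zscore(1, 5), "at least 2")
})

test_that("biome weighting averages per-biome distances by areal proportion", {
  # two latitude rows at 0 and 60 degrees: proportions 2/3 and 1/3
  g <- grid_spec(c(0, 60), seq(-135, 135, by = 90), 2000:2005)
  biomes <- make_biome_mask(g, 2)
  expect_equal(unname(biomes$proportions), c(2 / 3, 1 / 3), tolerance = 1e-9)
  mkmaps <- function(row1, row2) {
    m <- matrix(c(row1, row2), 2, 4, byrow = TRUE)
    structure(list(coef = list(sst = m, chl = m, mld = m),
                   significant = lapply(1:3, function(i)
                     matrix(TRUE, 2, 4)) |>
                     stats::setNames(c("sst", "chl", "mld")),
                   grid = g, years = g$years, alpha = 0.05),
              class = "coefficient_maps")
  }
  obs <- mkmaps(c(0, 1, 2, 3), c(0, 1, 2, 3))
  mod <- mkmaps(c(0, 1, 2, 3) + 1, c(0, 1, 2, 3) + 3)  # per-biome EMDs 1, 3
  e <- biome_weighted_emd(mod, obs, biomes)
  expect_equal(unname(e[["sst"]]), 2 / 3 * 1 + 1 / 3 * 3, tolerance = 1e-10)
  # identical maps give zero for every driver
  e0 <- biome_weighted_emd(obs, obs, biomes)
  expect_equal(as.numeric(e0), c(0, 0, 0))
  # empty significant sample on one side: biome dropped, weights renormalised
  mod2 <- mod
  mod2$significant$sst[2, ] <- FALSE
  expect_message(e2 <- biome_weighted_emd(mod2, obs, biomes), "renormalised")
  expect_equal(unname(e2[["sst"]]), 1)
})

test_that("model ranking combines mean and spread Z-scores with stable ties", {
  tab <- data.frame(model = rep(c("m1", "m2", "m3"), each = 3),
                    driver = rep(c("sst", "chl", "mld"), 3),
                    emd = c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  r <- rank_models(tab)
  expect_equal(r$model, c("m1", "m2", "m3"))
  expect_equal(r$combined_z, c(-0.5, 0, 0.5))      # sd channel degenerate
  expect_equal(r$rank, 1:3)
  expect_equal(mean(r$combined_z), 0, tolerance = 1e-12)
  # all-identical models: combined z all zero, ranked by model id
  tid <- tab; tid$emd <- 2
  rid <- rank_models(tid)
  expect_equal(rid$combined_z, c(0, 0, 0))
  expect_equal(rid$model, c("m1", "m2", "m3"))
  # permutation invariance of each model's rank
  perm <- tab[sample(nrow(tab)), ]
  rp <- rank_models(perm)
  expect_equal(rp[order(rp$model), "rank"], r[order(r$model), "rank"])
  # missing driver excludes the model
  expect_message(rmiss <- rank_models(tab[-1, ]), "excluding")
  expect_false("m1" %in% rmiss$model)
})

test_that("aggregation reports spread only when ranks are contested", {
  mk <- function(models, dn) {
    tab <- data.frame(model = rep(models, each = 3),
                      driver = rep(c("sst", "chl", "mld"),
                                   length(models)),
                      emd = rep(seq_along(models), each = 3))
    rank_models(tab, stats::setNames(dn, models))
  }
  r1 <- mk(c("a", "b"), c(-1, 1))
  r2 <- mk(c("a", "b"), c(-1, 1))     # same model at each rank: sd absent
  agg <- aggregate_rankings(list(r1, r2))
  expect_true(all(is.na(agg$delta_npp_sd)))
  r3 <- mk(c("b", "a"), c(1, -1))     # contested rank 1
  agg2 <- aggregate_rankings(list(r1, r3))
  expect_equal(agg2$n_models, c(2L, 2L))
  expect_false(any(is.na(agg2$delta_npp_sd)))
})
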