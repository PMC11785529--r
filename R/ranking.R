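#' Interquartile-range fence filter
#'
#' Retains values inside `[Q1 - k * IQR, Q3 + k * IQR]` with quartiles by
#' linear interpolation between order statistics (R's default type-7
#' convention), removing extreme outliers before distribution comparison.
#' Samples with fewer than 4 values are returned unfiltered, flagged
#' `attr(, "unfiltered")`.
#'
#' @param values Numeric sample (`NA` dropped).
#' @param k Fence multiplier (default 3, the extreme-outlier fence).
#' @return The retained values.
#' @examples
#' iqr_fence(c(1:8, 1000))   # removes 1000
#' @export
iqr_fence <- function(values, k = 3) {
  values <- values[!is.na(values)]
  if (length(values) < 4L)
    return(structure(values, unfiltered = TRUE))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

#' First Wasserstein (Earth mover's) distance between two samples
#'
#' The integral of the absolute difference between the empirical cumulative
#' distribution functions of `u` and `v`: symmetric, non-negative, zero iff
#' the empirical distributions coincide, and translation-equivariant
#' (shifting one sample by delta moves the distance by at most |delta|,
#' with equality when the samples are identical up to the shift).
#'
#' @param u,v Non-empty numeric samples (`NA` dropped).
#' @return The distance, in the units of the samples.
#' @examples
#' emd_1d(c(1, 2, 3, 4), c(2, 3, 4, 5))   # 1
#' @export
emd_1d <- function(u, v) {
  u <- u[!is.na(u)]; v <- v[!is.na(v)]
  if (length(u) == 0L || length(v) == 0L)
    stop("emd_1d requires non-empty samples", call. = FALSE)
  us <- sort(u); vs <- sort(v)
  all_v <- sort(c(us, vs))
  if (length(all_v) < 2L) return(0)
  dx <- diff(all_v)
  pts <- all_v[-length(all_v)]
  cdf_u <- findInterval(pts, us) / length(us)
  cdf_v <- findInterval(pts, vs) / length(vs)
  sum(abs(cdf_u - cdf_v) * dx)
}

#' Biome-weighted Earth mover's distance between coefficient maps
#'
#' For each driver and each biome, collects the significant coefficient
#' values of the model and observation maps within the biome, applies the
#' IQR fence to each side, computes [emd_1d()], and averages across biomes
#' weighted by areal proportion. Biomes where either side has no
#' significant sample are dropped and the weights renormalised (with a
#' message).
#'
#' @param model_maps,obs_maps [mlr_coefficient_maps()] results on the same
#'   grid.
#' @param biomes A [make_biome_mask()].
#' @param fence_k IQR fence multiplier (default 3).
#' @param drivers Drivers to compare.
#' @return Named numeric vector of weighted EMDs, one per driver, with a
#'   `dropped_biomes` attribute.
#' @export
biome_weighted_emd <- function(model_maps, obs_maps, biomes, fence_k = 3,
                               drivers = c("sst", "chl", "mld")) {
  stopifnot(inherits(model_maps, "coefficient_maps"),
            inherits(obs_maps, "coefficient_maps"),
            inherits(biomes, "biome_mask"))
  labels <- biomes$labels
  out <- stats::setNames(numeric(length(drivers)), drivers)
  dropped <- character(0)
  for (d in drivers) {
    emds <- weights <- numeric(0)
    for (b in names(biomes$proportions)) {
      in_b <- !is.na(labels) & labels == as.integer(b)
      mv <- model_maps$coef[[d]][in_b & model_maps$significant[[d]]]
      ov <- obs_maps$coef[[d]][in_b & obs_maps$significant[[d]]]
      if (length(mv) == 0L || length(ov) == 0L) {
        dropped <- c(dropped, paste0(d, ":", b))
        next
      }
      emds <- c(emds, emd_1d(iqr_fence(mv, fence_k),
                             iqr_fence(ov, fence_k)))
      weights <- c(weights, biomes$proportions[[b]])
    }
    if (length(emds) == 0L)
      stop("no biome with significant data on both sides for driver ", d,
           call. = FALSE)
    out[[d]] <- sum(emds * weights / sum(weights))
  }
  if (length(dropped) > 0)
    message("biome_weighted_emd: dropped empty biome(s) ",
            paste(dropped, collapse = ", "), "; weights renormalised")
  attr(out, "dropped_biomes") <- dropped
  out
}

#' Standard score of a value within an ensemble
#'
#' `z = (x - mu) / sigma` with `mu` and `sigma` the ensemble mean and
#' sample (n-1 denominator) standard deviation. A degenerate ensemble
#' (sigma = 0) yields z = 0 by convention.
#'
#' @param x Value(s) to score.
#' @param ensemble Ensemble values (length >= 2).
#' @return Z-score(s).
#' @export
zscore <- function(x, ensemble) {
  if (length(ensemble) < 2L)
    stop("zscore needs an ensemble of at least 2", call. = FALSE)
  s <- stats::sd(ensemble)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(ensemble)) / s
}

#' Rank an ensemble by combined EMD Z-scores
#'
#' For one observation algorithm and one jackknife assessment: each model's
#' EMDs across the three drivers are reduced to a mean and a sample
#' standard deviation; each channel is Z-scored across the model ensemble;
#' the two Z-scores are averaged with equal weight; models are ranked by
#' combined Z-score ascending (low = most observation-like). Ties are
#' broken by lower EMD mean, then by model identifier. Models missing a
#' driver EMD are excluded with a message.
#'
#' @param emd_table Data frame with columns `model`, `driver`, `emd`
#'   covering all drivers for each model.
#' @param delta_npp Named numeric (by model) of each model's projected
#'   change in globally integrated NPP (Pg C per year), carried through to
#'   the ranking read-out; optional.
#' @return An `ensemble_ranking` data frame: `model`, `emd_mean`,
#'   `emd_sd`, `z_mean`, `z_sd`, `combined_z`, `rank`, `delta_npp`, sorted
#'   by rank.
#' @export
rank_models <- function(emd_table, delta_npp = NULL) {
  stopifnot(all(c("model", "driver", "emd") %in% names(emd_table)))
  drivers <- unique(emd_table$driver)
  models <- unique(emd_table$model)
  complete <- vapply(models, function(m)
    all(drivers %in% emd_table$driver[emd_table$model == m]) &&
      !anyNA(emd_table$emd[emd_table$model == m]), TRUE)
  if (any(!complete)) {
    message("rank_models: excluding model(s) with missing driver EMDs: ",
            paste(models[!complete], collapse = ", "))
    models <- models[complete]
  }
  if (length(models) < 2L)
    stop("ranking needs at least 2 complete models", call. = FALSE)
  emd_mean <- vapply(models, function(m)
    mean(emd_table$emd[emd_table$model == m]), numeric(1))
  emd_sd <- vapply(models, function(m)
    stats::sd(emd_table$emd[emd_table$model == m]), numeric(1))
  z_mean <- zscore(emd_mean, emd_mean)
  z_sd <- zscore(emd_sd, emd_sd)
  combined <- (z_mean + z_sd) / 2
  ord <- order(combined, emd_mean, models)
  out <- data.frame(model = models[ord],
                    emd_mean = emd_mean[ord], emd_sd = emd_sd[ord],
                    z_mean = z_mean[ord], z_sd = z_sd[ord],
                    combined_z = combined[ord],
                    rank = seq_along(models))
  out$delta_npp <- if (is.null(delta_npp)) NA_real_ else
    unname(delta_npp[out$model])
  rownames(out) <- NULL
  class(out) <- c("ensemble_ranking", "data.frame")
  out
}

#' Summarise rankings across jackknife assessments
#'
#' For each rank position, the mean and standard deviation of the projected
#' NPP change of the model(s) occupying that rank across assessments. When
#' a single model holds the rank in every assessment the standard deviation
#' is reported as `NA` (no spread to show).
#'
#' @param rankings List of [rank_models()] results (one per assessment).
#' @return Data frame `rank`, `delta_npp_mean`, `delta_npp_sd`, `n_models`
#'   (distinct models seen at that rank), `models`.
#' @export
aggregate_rankings <- function(rankings) {
  stopifnot(length(rankings) >= 1,
            all(vapply(rankings, inherits, TRUE, "ensemble_ranking")))
  ranks <- sort(unique(unlist(lapply(rankings, `[[`, "rank"))))
  out <- do.call(rbind, lapply(ranks, function(r) {
    rows <- do.call(rbind, lapply(rankings, function(rk) rk[rk$rank == r, ]))
    mods <- unique(rows$model)
    data.frame(rank = r,
               delta_npp_mean = mean(rows$delta_npp),
               delta_npp_sd = if (length(mods) > 1L)
                 stats::sd(rows$delta_npp) else NA_real_,
               n_models = length(mods),
               models = paste(sort(mods), collapse = ","))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ensemble_ranking <- function(x, digits = 3, ...) {
  cat("<ensemble_ranking>", nrow(x), "models (rank 1 = most observation-like)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
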