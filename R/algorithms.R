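# Satellite NPP algorithm skeletons. Each family keeps the published
# multiplicative structure; the inner parameterizations (temperature
# function, light limitation, carbon conversion, absorption inner function)
# are pluggable strategy functions whose defaults follow the algorithms'
# source publications. Values in mg C m-2 d-1 throughout.

#' Optimal chlorophyll-normalised photosynthetic rate
#'
#' Temperature dependence of the VGPM family. The `eppley` variant is a pure
#' exponential in SST (`1.54 * 10^(0.0275 * SST - 0.07)`); the `behrenfeld`
#' variant is the source publication's seventh-order polynomial with its
#' range clamps (1.13 below -1 degC, 4.00 above 28.5 degC).
#'
#' @param sst Sea surface temperature (degC), any numeric shape.
#' @param variant `"eppley"` or `"behrenfeld"`.
#' @return P^B_opt in mg C (mg Chl)-1 h-1, same shape as `sst`.
#' @export
popt_vgpm <- function(sst, variant = c("eppley", "behrenfeld")) {
  variant <- match.arg(variant)
  stopifnot(all(is.finite(sst)))
  if (variant == "eppley") {
    1.54 * 10^(0.0275 * sst - 0.07)
  } else {
    p <- 1.2956 + 2.749e-1 * sst + 6.17e-2 * sst^2 - 2.05e-2 * sst^3 +
      2.462e-3 * sst^4 - 1.348e-4 * sst^5 + 3.4132e-6 * sst^6 -
      3.27e-8 * sst^7
    p[sst < -1] <- 1.13
    p[sst > 28.5] <- 4.00
    pmax(p, 0)
  }
}

# parameterized light term: ratio of realised to maximum potential NPP
fpar_vgpm_default <- function(par) 0.66125 * par / (par + 4.1)

#' Default parameter sets for the NPP algorithms
#'
#' Strategy objects holding the pluggable inner parameterizations. Replace
#' any element to experiment with alternative closures.
#'
#' `vgpm_params`: `popt_variant` and the light-limitation handle `fpar`
#' (default `0.66125 * PAR / (PAR + 4.1)`, bounded in `[0, 1]`).
#'
#' `cbpm_params`: carbon conversion `cph_from_bbp` (default
#' `13000 * (bbp443 - 0.00035)`, clamped at zero below the offset), maximum
#' growth rate `mu_max` (2 d-1), the chlorophyll-to-carbon saturation curve
#' `chlc_sat(Ig)` (default `0.022 + 0.023 * exp(-3 Ig)`), the light term
#' `fpar(Ig)` (default `1 - exp(-5 Ig)`) and the trapezoid step `dz` (1 m)
#' for the depth-resolved variant. The growth irradiance Ig is the PAR flux
#' attenuated by Kd490 to the evaluation depth (mixed-layer midpoint for the
#' depth-averaged variant).
#'
#' `abpm_params`: the inner function `inner(aph443, kd490, zeu, par)`
#' mapping absorption and light to carbon fixation; the default integrates
#' the absorbed light field analytically,
#' `psi * aph443 * PAR * (1 - exp(-kd490 * zeu)) / kd490` with `psi` = 150
#' mg C (mol photon)-1 m.
#'
#' `cafe_params`: carbon-conversion efficiency `phi_max` (0.35,
#' dimensionless in (0, 1]), light-saturation parameter `ek` (40 mol photon
#' m-2 d-1) and the energy-absorption closure `q_par(inputs)` used when the
#' scene does not already provide `q_par`.
#'
#' @param popt_variant Temperature function for [popt_vgpm()].
#' @return A named list of parameters/functions.
#' @name algorithm-params
NULL

#' @rdname algorithm-params
#' @export
vgpm_params <- function(popt_variant = "eppley") {
  list(popt_variant = popt_variant, fpar = fpar_vgpm_default)
}

#' @rdname algorithm-params
#' @export
cbpm_params <- function() {
  list(mu_max = 2,
       cph_from_bbp = function(bbp) pmax(13000 * (bbp - 0.00035), 0),
       chlc_sat = function(ig) 0.022 + 0.023 * exp(-3 * ig),
       fpar = function(ig) 1 - exp(-5 * ig),
       dz = 1)
}

#' @rdname algorithm-params
#' @export
abpm_params <- function() {
  list(inner = function(aph443, kd490, zeu, par)
    150 * aph443 * par * (1 - exp(-kd490 * zeu)) / kd490)
}

#' @rdname algorithm-params
#' @export
cafe_params <- function() {
  list(phi_max = 0.35, ek = 40,
       q_par = function(inputs)
         12.011 * inputs$aph443 * inputs$par *
           (1 - exp(-inputs$kd490 * inputs$zeu)) / inputs$kd490)
}

check_nonnegative <- function(inputs, fields) {
  for (f in fields) {
    v <- inputs[[f]]
    if (is.null(v)) stop("missing input field '", f, "'", call. = FALSE)
    if (any(v < 0, na.rm = TRUE))
      stop("negative values in input field '", f, "'", call. = FALSE)
  }
}

#' Vertically generalised production model (VGPM)
#'
#' `NPP = Chl * P^B_opt(SST) * DL * f(PAR) * Zeu`: linear in chlorophyll,
#' day length and euphotic depth, with all temperature dependence inside
#' `P^B_opt` and all light limitation inside `f(PAR)`.
#'
#' @param inputs Named list/scene with `chl` (mg m-3), `sst` (degC), `par`
#'   (mol photon m-2 d-1), `day_length` (h), `zeu` (m); elements may be
#'   scalars or matrices of a common shape.
#' @param params A [vgpm_params()] list.
#' @return NPP (mg C m-2 d-1), same shape as the inputs.
#' @export
npp_vgpm <- function(inputs, params = vgpm_params()) {
  check_nonnegative(inputs, c("chl", "par", "day_length", "zeu"))
  inputs$chl * popt_vgpm(inputs$sst, params$popt_variant) *
    inputs$day_length * params$fpar(inputs$par) * inputs$zeu
}

# growth irradiance at depth z: daily PAR flux attenuated by Kd490
growth_irradiance <- function(par, day_length, kd490, z)
  (par / day_length) * exp(-kd490 * z)

#' Carbon-based production model (CbPM)
#'
#' Phytoplankton carbon is derived from particulate backscatter; growth rate
#' from the chlorophyll-to-carbon ratio relative to its light-dependent
#' saturation value, capped at `mu_max`. The `behrenfeld` variant is depth
#' averaged, `NPP = C_ph * mu * f(PAR) * Zeu`, with the growth irradiance
#' evaluated at the mixed-layer midpoint; the `westberry` variant resolves
#' depth, integrating `C_ph(z) * mu(z) * f(Ig(z))` over `[0, Zeu]` by the
#' trapezoid rule on a fixed `dz` grid, treating water below the nitracline
#' `z_no3` as nutrient replete.
#'
#' @param inputs Scene with `chl`, `bbp443`, `par`, `day_length`, `kd490`,
#'   `mld`, `zeu` and (for `westberry`) `z_no3`.
#' @param params A [cbpm_params()] list.
#' @param variant `"behrenfeld"` or `"westberry"`.
#' @return NPP (mg C m-2 d-1).
#' @export
npp_cbpm <- function(inputs, params = cbpm_params(),
                     variant = c("behrenfeld", "westberry")) {
  variant <- match.arg(variant)
  check_nonnegative(inputs, c("chl", "bbp443", "par", "day_length",
                              "kd490", "zeu"))
  cph <- params$cph_from_bbp(inputs$bbp443)
  chlc <- ifelse(cph > 0, inputs$chl / cph, 0)
  if (variant == "behrenfeld") {
    check_nonnegative(inputs, "mld")
    ig <- growth_irradiance(inputs$par, inputs$day_length, inputs$kd490,
                            inputs$mld / 2)
    mu <- params$mu_max * pmin(1, chlc / params$chlc_sat(ig))
    return(cph * mu * params$fpar(ig) * inputs$zeu)
  }
  check_nonnegative(inputs, "z_no3")
  shp <- if (is.null(dim(cph))) length(cph) else dim(cph)
  flat <- function(x) rep_len(as.vector(x), prod(shp))
  zeu <- flat(inputs$zeu); par <- flat(inputs$par)
  dl <- flat(inputs$day_length); kd <- flat(inputs$kd490)
  zno3 <- flat(inputs$z_no3); cphv <- flat(cph); chlcv <- flat(chlc)
  out <- vapply(seq_len(prod(if (is.numeric(shp)) shp else 1)), function(i) {
    z <- unique(c(seq(0, zeu[i], by = params$dz), zeu[i]))
    ig <- growth_irradiance(par[i], dl[i], kd[i], z)
    ratio <- pmin(1, chlcv[i] / params$chlc_sat(ig))
    ratio[z > zno3[i]] <- 1           # nutrient replete below the nitracline
    f <- cphv[i] * params$mu_max * ratio * params$fpar(ig)
    sum(diff(z) * (f[-1] + f[-length(f)]) / 2)
  }, numeric(1))
  if (!is.null(dim(cph))) dim(out) <- dim(cph)
  out
}

#' Absorption-based production model (AbPM)
#'
#' `NPP = f(aph443, Kd490-attenuated light field, Zeu, PAR)` with `f` the
#' pluggable inner function; NPP is zero whenever phytoplankton absorption
#' or PAR is zero.
#'
#' @param inputs Scene with `aph443`, `kd490`, `zeu`, `par`.
#' @param params An [abpm_params()] list; `params$inner` must be a function.
#' @return NPP (mg C m-2 d-1).
#' @export
npp_abpm <- function(inputs, params = abpm_params()) {
  if (!is.function(params$inner))
    stop("abpm params$inner must be a function", call. = FALSE)
  check_nonnegative(inputs, c("aph443", "kd490", "zeu", "par"))
  params$inner(inputs$aph443, inputs$kd490, inputs$zeu, inputs$par)
}

#' Carbon, absorption and fluorescence euphotic-resolving model (CAFE)
#'
#' `NPP = Q_PAR * Phi_mu_max * tanh(E_k / PAR)`: energy absorption times
#' carbon-conversion efficiency times a saturating light term, so NPP is
#' bounded above by `Q_PAR * Phi_mu_max`. Where PAR is zero the tanh
#' argument diverges and the light term is taken at its saturating limit of
#' one (logged via a message).
#'
#' @param inputs Scene with `par` and either a precomputed `q_par` field or
#'   the `aph443`, `kd490`, `zeu` fields the default closure needs.
#' @param params A [cafe_params()] list.
#' @return NPP (mg C m-2 d-1).
#' @export
npp_cafe <- function(inputs, params = cafe_params()) {
  check_nonnegative(inputs, "par")
  q <- if (!is.null(inputs$q_par)) inputs$q_par else params$q_par(inputs)
  if (any(q < 0, na.rm = TRUE))
    stop("negative energy absorption", call. = FALSE)
  light <- tanh(params$ek / inputs$par)
  zero <- inputs$par == 0
  if (any(zero, na.rm = TRUE)) {
    message("npp_cafe: PAR = 0 at ", sum(zero, na.rm = TRUE),
            " cells; light term saturated at 1")
    light[zero] <- 1
  }
  q * params$phi_max * light
}

#' Evaluate one of the six named NPP algorithms on a scene
#'
#' @param name One of `"eppley_vgpm"`, `"behrenfeld_vgpm"`,
#'   `"behrenfeld_cbpm"`, `"westberry_cbpm"`, `"lee_abpm"`, `"silsbe_cafe"`.
#' @param inputs A scene as from [make_ocean_colour_scene()].
#' @param params Optional parameter list overriding the family default.
#' @return NPP field (mg C m-2 d-1).
#' @export
npp_algorithm <- function(name, inputs, params = NULL) {
  name <- match.arg(name, c("eppley_vgpm", "behrenfeld_vgpm",
                            "behrenfeld_cbpm", "westberry_cbpm",
                            "lee_abpm", "silsbe_cafe"))
  switch(name,
    eppley_vgpm = npp_vgpm(inputs, params %||% vgpm_params("eppley")),
    behrenfeld_vgpm = npp_vgpm(inputs,
                               params %||% vgpm_params("behrenfeld")),
    behrenfeld_cbpm = npp_cbpm(inputs, params %||% cbpm_params(),
                               "behrenfeld"),
    westberry_cbpm = npp_cbpm(inputs, params %||% cbpm_params(),
                              "westberry"),
    lee_abpm = npp_abpm(inputs, params %||% abpm_params()),
    silsbe_cafe = npp_cafe(inputs, params %||% cafe_params()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
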