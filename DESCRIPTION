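Package: npprank
Title: Ranking Earth System Model Ocean Productivity Projections Against
    Satellite Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate ensembles of Earth-system-model projections of
    marine net primary production (NPP) against satellite ocean-colour NPP
    algorithms. Implements six NPP algorithm skeletons (Eppley-VGPM,
    Behrenfeld-VGPM, Behrenfeld-CbPM, Westberry-CbPM, Lee-AbPM, Silsbe-CAFE)
    with pluggable inner parameterizations; jackknifed per-pixel trend
    estimation with a normality-gated switch between Huber robust regression
    and the Mann-Kendall/Theil-Sen estimator; per-pixel multiple linear
    regression of mean-normalised NPP on sea surface temperature,
    chlorophyll-a and mixed layer depth with Newey-West
    heteroskedasticity-and-autocorrelation-consistent inference; and a
    biome-weighted Earth mover's (first Wasserstein) distance Z-score scheme
    that ranks ensemble members by the similarity of their NPP-driver
    relationships to observations. A seeded synthetic-data generator with
    known per-pixel coefficients, trends and AR(1) noise provides ground
    truth for end-to-end recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
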