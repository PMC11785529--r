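# npprank

Ranking Earth-system-model projections of marine net primary production
(NPP) against satellite ocean-colour algorithms.

## The problem

Climate models disagree about the future of marine NPP — projections of
the change in globally integrated NPP by 2100 span declines and increases,
and the ensemble mean carries a standard deviation several times its
magnitude. Direct comparison with the ~26-year satellite record does not
settle the question, because satellite NPP algorithms themselves disagree
about the contemporary trend. `npprank` implements a *process-based*
alternative for scientists evaluating model ensembles: compare not the NPP
fields but the emergent relationships between NPP and its environmental
drivers — sea surface temperature (SST), chlorophyll-a (CHL) and mixed
layer depth (MLD) — and rank models by how closely their relationships
match the observed ones.

## The method

Per ocean pixel, annual-mean series are divided by their mean and NPP is
regressed on the three drivers,

```
NPP*(t) = b0 + b_SST · SST*(t) + b_CHL · CHL*(t) + b_MLD · MLD*(t) + e(t)
```

(the `*` marking mean-normalised series), with Newey–West
heteroskedasticity-and-autocorrelation-consistent inference at the
rule-of-thumb lag `floor(4 (T/100)^(2/9))`. Observational records are
jackknifed — every contiguous 20-year window of the 26-year record, seven
assessments — so trend sensitivity to start/end years propagates into the
result. Within each ocean biome the significant coefficients of a model
and of an observational product are fenced (quartiles ± 3×IQR) and
compared by the first Wasserstein distance,

```
W1(u, v) = ∫ |U(x) − V(x)| dx ,
```

biome distances are averaged with areal-proportion weights, the three
driver distances are reduced per model to a mean and standard deviation,
both channels are Z-scored across the ensemble,
`z = (x − μ)/σ`, and models are ranked by the equally weighted combined
Z-score (low = most observation-like). The read-out is each model's
projected change in globally integrated NPP (ΔNPP, Pg C yr⁻¹) at each rank
position across assessments.

Supporting machinery includes six satellite NPP algorithm skeletons
(Eppley-VGPM, Behrenfeld-VGPM, Behrenfeld-CbPM, Westberry-CbPM, Lee-AbPM,
Silsbe-CAFE) with pluggable inner parameterizations, normality-gated
per-pixel trend estimation (D'Agostino–Pearson test routing to a Huber
regression, ε = 1.35, or to Mann–Kendall/Theil–Sen), mixed-layer-depth
derivation from density profiles (0.03 kg m⁻³ criterion, 10 m reference),
and a seeded synthetic-data generator whose hidden truth (per-pixel
coefficients, trends, AR(1) noise, per-model coefficient shifts) makes
every stage's output checkable. See the methods vignette
(`vignettes/model-ranking-methods.Rmd`) for assumptions, defaults and
limitations.

## Worked example

Run the full synthetic-to-ranking pipeline under its default study
conditions (36×18 grid, 1998–2023, two observation-like products, five
pseudo-models carrying coefficient shifts of increasing magnitude and
prescribed ΔNPP values):

```r
library(npprank)
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
print(res)
```

```
<npp_ranking> 2 products x 7 assessments x 5 models
Regional NPP trends (% per year):
 obs_1  obs_2
-0.176 -0.184

Ranking summary for obs_1 :
 rank delta_npp_mean delta_npp_sd n_models  models
    1             -3           NA        1 model_1
    2             -2           NA        1 model_2
    3             -1           NA        1 model_3
    4              0           NA        1 model_4
    5              1           NA        1 model_5
```

Reading the output: both synthetic observation products show a declining
regional NPP trend of about −0.18% yr⁻¹ (the generator's prescribed driver
trends acting through the prescribed coefficients). The ranking recovers
the planted structure exactly — model 1 carries the smallest coefficient
shifts away from the observational truth, so it ranks first in all seven
jackknife assessments (hence no ΔNPP spread at any rank), and the ΔNPP
read-out at rank 1 is that model's prescribed −3 Pg C yr⁻¹.

A command-line front end over the same functions is provided at
`inst/cli/npprank.R` (subcommands `simulate`, `trends`, `mlr`, `rank`,
`run-all`).

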