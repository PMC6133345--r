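# availbias

Availability-bias-corrected abundance estimation for diving marine animals
surveyed from the air.

## The problem

Aerial line-transect surveys can only detect animals that are in the top
metre or so of the water column as the plane passes. A deep-diving species
such as the blue shark may spend most of its time below that layer, and the
fraction of time it is *available* for detection changes with habitat: far
more surface time over the continental shelf than in deep off-shelf water.
Ignoring availability understates abundance severalfold; applying a single
average correction misplaces abundance in space whenever habitats mix. This
package is for quantitative ecologists who need absolute abundance from
aerial surveys of diving species, corrected with *modelled*, habitat-specific
availability estimated from electronic tag data.

## The models

Three stages, each exposed as ordinary R functions:

1. **Availability** — the proportion *y* of each 6-hour tag bin spent at
   0–1 m depth is modelled with a Bayesian zero-one-inflated beta (ZOIB)
   mixed model,

   *f(y) = p₀·[y=0] + (1−p₀)p₁·[y=1] + (1−p₀)(1−p₁)·Beta(y; μφ, (1−μ)φ)*,

   with logit-linear shelf and time-of-day effects in all three components
   and a shark×day random intercept (u ~ N(0, σ²)) in the mean. Fitting is
   by an adaptive Metropolis-within-Gibbs sampler with interweaving sweeps
   (`fit_zoib()`); models are compared by DIC and per-stratum availability
   is predicted with the random effect integrated out
   (`predict_availability()`).
2. **Perception** — a hazard-rate detection function
   *g(x) = 1 − exp(−(x/σ)^−b)* (or half-normal), with sighting-condition
   covariates scaling σ log-linearly, fitted to perpendicular distances by
   maximum conditional likelihood out to w = 500 m (`fit_detection()`),
   checked by Cramér–von Mises goodness of fit (`cvm_gof()`).
3. **Abundance** — a density surface model: Tweedie log-link GAM of
   availability-divided segment counts on a spatial smooth plus habitat
   smooths, offset log(2·w·L·p̂), REML with γ = 1.4 and shrinkage term
   selection (`fit_dsm()`); grid prediction with coefficient-simulation CVs
   and lognormal intervals (`predict_abundance()`).

A synthetic-data module (`simulate_tags()`, `simulate_survey()`,
`make_fixture_suite()`) generates tag and survey datasets with known truth,
so the whole chain is testable without any field data.

## Worked example

The staged pipeline on a synthetic study (two tagged sharks; one summer
zig-zag aerial survey over a 300×300 km shelf/off-shelf region):

```r
library(availbias)
cfg <- read_pipeline_config()        # defaults; YAML overrides supported
cfg$output_dir <- "blue_shark_run"
cfg$seed <- 7
for (stage in c("sim-tags", "sim-survey", "prep-tags", "fit-availability",
                "fit-detection", "fit-dsm", "predict")) {
  run_stage(stage, cfg)
}
pipeline_report(cfg$output_dir)
```

which logs each stage and prints:

```
[availbias] sim-tags: wrote blue_shark_run/tags.csv (760 bins)
[availbias] sim-survey: 79 sightings on 7206 km of trackline
[availbias] prep-tags: 744 availability observations (pooled mean 0.39)
[availbias] fit-availability: on 0.668 / off 0.191 (DIC delta 13.19)
[availbias] fit-detection: selected 'null' (mean p 0.358)
[availbias] predict: 3 scenario estimate(s) written

Abundance estimates by availability scenario
    scenario N_hat   cv ci_low ci_high ratio_to_uncorrected
 uncorrected  2742 0.12   2162    3476                 1.00
     average  7030 0.12   5545    8914                 2.56
    modelled  6200 0.12   4879    7877                 2.26

Detection function comparison
 model     aic cvm_p delta_aic selected
  null 899.089 0.987  0.000000     TRUE
 cloud 902.900 0.990  3.811122    FALSE
```

Reading the output: the tagged sharks were at the surface 39% of the time
overall, but the fitted ZOIB model splits this into 0.67 on-shelf vs 0.19
off-shelf. The uncorrected survey estimate (2,742 animals) is what a naive
strip analysis of the sightings supports; dividing counts by the modelled,
habitat-specific availability raises it to 6,200 (CV 0.12, lognormal 95% CI
4,879–7,877) — a 2.3× correction here, and close to the generator's true
abundance of ~6,000 for this seed. The `average` scenario divides by the
single pooled constant instead; because the fit is log-linear that is an
exact rescaling of the uncorrected estimate (7030 × 0.39 = 2742). The
detection table shows the candidate detection functions ranked by AIC with
their goodness-of-fit p-values; a model failing the p ≥ 0.10 floor would be
passed over in favour of the next candidate within 10 AIC units.

The same functions work on real CSV inputs (tag depth-bin records, effort
fixes, sightings with distances, an environmental grid) by pointing
`cfg$paths` at them — see `?run_stage` for the stage contracts, and
`inst/cli/availbias.R` for a thin command-line wrapper
(`Rscript availbias.R <stage> --config cfg.yaml --seed N`).

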