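# cropbiodiv

Agriculture drives local biodiversity loss both by converting natural
habitat to farmland (**expansion**) and by raising yields on existing
farmland (**intensification**). Which strategy is less damaging for a
given production target is a landscape-dependent question at the heart of
the land-sparing/land-sharing debate. **cropbiodiv** is an R package for
analysts working with PREDICTS-style site-level survey collations and
co-registered agricultural raster layers (yields, harvested-area
fractions, natural-habitat cover, climate). It implements the full
analysis chain as tidyverse-native, tested functions, plus a
synthetic-data generator with known ground truth so that every stage can
be validated end to end without external downloads.

## What it computes

**Site metrics.** Sampled species richness; effort-corrected total
abundance, rescaled by the within-study maximum and log_e-transformed
(`log(v / max + 0.01)`); and RCAR, the relative community
abundance-weighted average range size, `Σ aᵢrᵢ / Σ aᵢ` (log10 for
modelling) — a biotic-homogenization proxy: higher values mean communities
dominated by widespread species.

**Covariates and weights.** Shannon crop diversity `H′ = −Σ pᵢ ln pᵢ`;
landscape classification (<30% natural vegetation = human-modified, >70%
= natural) combined with land use into a four-category variable; tropical
vs non-tropical at 23.5°; one-cell (Moore ring) buffer–focal differences;
duration of substantial human modification; skew-correcting log
transforms (left-skew: `V_t = log_e(C − V)` with `C = ceiling(max +
margin)`); standardization frozen at fit time; correlation screening at
|r| > 0.6 with priority yield → natural habitat → subsistence yield; and
per-site weights `RA_C = A_C / Σ Aᵢ`, rescaled so the mean weight is
exactly 1.

**Models.** Weighted mixed-effects models of the three responses
(Poisson + observation-level random effect for richness; Gaussian for the
transformed abundance and RCAR), with random intercepts for study and
block-in-study, maximum-likelihood estimation, backward stepwise
selection by likelihood-ratio tests at p = 0.05, marginal/conditional
pseudo-R², 1,000-draw multivariate-normal fixed-effect summaries as
percentage changes, and JSON model serialization.

**Counterfactuals.** Closing yield gaps (attainable yield = area-weighted
95th percentile within precipitation × growing-degree-day zones) with
per-pixel aggregation `BD = Σᵢ pᵢ(BD_crop p_crop + BD_pv p_pv)`; and
production-matched expansion vs intensification per pixel (`BD = BD_crop
p_crop + BD_pv p_pv`), with uniform and patterned intensification (2% on
50%, 10% on 10%, 10% with partial restoration), validity masking, and
area-weighted winner fractions per crop and metric.

## Worked example

```r
library(cropbiodiv)

cfg  <- sim_config(grid_rows = 30, grid_cols = 30, n_studies = 12, seed = 1)
grid <- generate_landscape_grid(cfg)
gen  <- generate_sites(grid, config = cfg)

dataset <- assemble_model_dataset(gen$sites, grid, crop = "maize")
fit <- fit_glmm(bd_model_spec("richness",
                              fixed = c("yield", "natural", "land_use")),
                dataset)
tidy(fit)
#> # A tibble: 4 × 5
#>   term             estimate std.error statistic   p.value
#>   <chr>               <dbl>     <dbl>     <dbl>     <dbl>
#> 1 (Intercept)         2.73     0.121      22.5  3.48e-112
#> 2 yield              -0.203    0.0462     -4.39 1.12e-  5
#> 3 natural             0.104    0.0434      2.40 1.65e-  2
#> 4 land_usecropland   -0.468    0.0483     -9.70 3.11e- 22
```

The world was generated with true coefficients (2.5, −0.25, +0.15, −0.4),
all recovered within two standard errors: richness falls with landscape
yield, rises with natural-habitat cover, and cropland sites hold
`100·(exp(−0.468) − 1) ≈ −37%` of the species of primary-vegetation
sites. `pseudo_r2(fit, dataset)` reports marginal 0.25 and conditional
0.84 — most variation sits in the study/block random effects, as is
typical for multi-source survey collations.

```r
at     <- attainable_yield(grid, "maize")
closed <- close_yield_gaps(grid, list(maize = at))
cm <- pct_change_map(project_grid_bd(closed, fit, crops = "maize"),
                     project_grid_bd(grid,   fit, crops = "maize"))
summarize_changes(cm)
#> # A tibble: 1 × 5
#>   frac_decreasing  mean median frac_zero n_valid
#>             <dbl> <dbl>  <dbl>     <dbl>   <int>
#> 1           0.958 -20.5  -19.0    0.0422     616

attr(compare_strategies(grid, "maize", list(richness = fit),
                        delta = 0.01), "summary")
#> # A tibble: 1 × 4
#>   metric   intensification_better_pct expansion_better_pct tie_pct
#>   <chr>                         <dbl>                <dbl>   <dbl>
#> 1 richness                        100                    0       0
```

Under this fitted model (yield hurts richness, natural habitat helps),
closing yield gaps lowers richness in 95.8% of cultivated pixels (mean
−20.5%); yet for a 1% production increase, intensification still beats
expansion everywhere, because the marginal habitat loss of expansion
outweighs the marginal yield effect. `autoplot()` methods draw the change
and winner maps; `run_pipeline(pipeline_config(...))` chains
simulate → prepare → fit → project → compare and writes all artefacts
(CSV/JSON) with a reproducibility manifest.

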