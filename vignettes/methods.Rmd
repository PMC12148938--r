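---
title: "Models and methods behind cropbiodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cropbiodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cropbiodiv)
```

cropbiodiv implements a space-for-time analysis of how cropland expansion
and intensification affect local biodiversity, as a reusable, fully tested
pipeline. This vignette is the package's own account of the models, the
choices that were genuinely open, and what the tests do and do not show.

## The three biodiversity responses

Community samples are summarised per site by three metrics.

**Sampled species richness** is the count of taxa recorded with positive
abundance (or a presence flag). It is modelled with a Poisson
generalized linear mixed model on a log link. Because site-level counts
from heterogeneous surveys are overdispersed relative to Poisson, the
richness model carries an observation-level random intercept for site; a
negative-binomial alternative (dropping that random effect) is available
through the same interface.

**Total abundance** sums the per-taxon abundance measures, after an effort
correction: where the measure is effort-sensitive and effort differs among
sites of a study, the sum is divided by the site's effort relative to the
most-sampled site in that study. Because abundance units differ wildly
across studies (counts, cover, biomass), values are rescaled by the
maximum abundance within each study and then log_e-transformed with an
offset of 0.01 for zeros; the Gaussian model works on that scale. Studies
whose maximum abundance is zero cannot be rescaled and are flagged
`usable = FALSE` rather than silently dropped.

**RCAR** (relative community abundance-weighted average range size) proxies
biotic homogenization: it is the abundance-weighted arithmetic mean of the
range sizes of the taxa present, `sum(a_i r_i) / sum(a_i)`, modelled on a
log10 scale. We read the "relative" in RCAR as relative-abundance
weighting, so the metric is invariant to a uniform rescaling of
abundances and bounded by the smallest and largest range present; whether
the original metric divided by a regional reference is not restated in the
source literature, so the arithmetic weighted mean is a documented package
choice, not an assertion about the original. Occurrence-only samples
degrade gracefully to an unweighted mean.

## Covariate engineering

One row per site, with the engineered covariates of the yield–biodiversity
model: the focal crop's landscape yield; percentage of natural habitat;
subsistence yield (an agricultural-suitability proxy); Shannon crop
diversity `H' = -sum(p_i ln p_i)` over each crop's share of the pixel's
cropland; buffer–focal differences (the mean over the Moore ring of up to
eight neighbouring cells minus the focal value — our reading of a one-cell
"~10 km" buffer at ~10 km cells; whether the original used diagonal
neighbours or a circular disc is unstated); duration of substantial human
modification (years since 30% of the cell came under human use; cells
that never crossed get 0 years, which the left-skew transform then places
consistently at the "latest modification" end); mean annual temperature;
and annual precipitation.

Right-skewed covariates get `log_e(V + 0.01)`; left-skewed ones get
`V_t = log_e(C - V)`, which flips the order of values and the sign of
downstream effects. The constant `C` defaults to `ceiling(max + margin)`;
the conventional published constant for the duration variable (2,005) is
not reproduced by plain ceiling from 1,981.6 + 20, so `C` is accepted as a
user override. For the duration covariate the package fits `C` from the
full raster rather than the training sites, so counterfactual grids stay
inside the transform's domain. All continuous covariates are standardized
(mean 0, sd 1), and the transform plus standardization state is frozen at
fit time and reused verbatim for every projection — never refitted on
counterfactual grids.

Pairs of continuous covariates with |Pearson r| > 0.6 are screened
greedily by descending |r|, removing the lower-priority member (priority:
yield, natural habitat, subsistence; the source procedure names the
priorities but not an algorithm, so greedy-by-|r| is the package's
deterministic choice). Sites are weighted by the focal crop's share of the
pixel's total harvested area, rescaled so the mean weight over included
sites is exactly 1; the mixed-model backend treats weights as frequency
weights, which is precisely why the mean-1 rescaling matters — only
relative weights affect the fit.

Classification conventions: landscapes under 30% natural vegetation are
"human-modified", over 70% "natural" (strict inequalities; exactly
0.30/0.70 falls in the excluded intermediate band, which the conversion
models do not use). Latitudes within 23.5° of the equator are tropical;
the boundary itself is assigned tropical — a measure-zero convention.

## Mixed-effects models and selection

All models carry random intercepts for study identity and for spatial
block nested within study, and are estimated by maximum likelihood (not
REML) with glmmTMB, because likelihood-ratio tests on fixed effects
require ML. Backward stepwise selection repeatedly removes the currently
droppable term with the largest LRT p-value above alpha = 0.05,
refitting after each drop; marginality is respected (a main effect is
locked while an interaction containing it is retained), one term is
dropped per step (the original procedure does not state one-versus-all
dropping; one-per-step is pinned), and ties prefer the higher-order term,
then lexicographic order, so selection is deterministic. If an initial
model fails to converge, a prespecified interaction list can be dropped up
front — the documented fallback for data-poor responses. An alpha of 1 is
treated as the degenerate threshold under which every droppable term is
removed.

Pseudo-R² follows the variance-partitioning convention: marginal =
fixed-effect variance over fixed + random + distribution-specific
variance; conditional adds the random-effect variances to the numerator.
For the log-link count families the distribution-specific variance uses
the lognormal approximation `ln(1 + 1/lambda)` with
`lambda = exp(beta_0 + sigma_re^2/2)` — one documented choice among the
published options.

Effect summaries draw the fixed effects 1,000 times from the full
multivariate normal implied by the variance-covariance matrix (the
source wording suggests multivariate rather than independent marginals;
implemented so), convert contrasts to percentage change on the response
scale (`100 (e^d - 1)` under a log link), and report the median with the
2.5th and 97.5th percentiles. Draws use a symmetric eigendecomposition
with eigenvalues below -1e-10 an error and small negatives clipped to
zero. Projections use population-level predictions — random effects at
zero — the standard choice left implicit in the source; predictions
outside the training covariate range are flagged per pixel but not
clamped.

## Projections and scenarios

**Closing yield gaps.** Attainable yield is the area-weighted 95th
percentile of observed yields within climate zones — an n x n grid of
quantile bins over annual precipitation and growing-degree days. On
synthetic grids growing-degree days are proxied by mean annual temperature
bins (no daily series exists by design); real-GDD ingestion is a reader
concern. The weighted percentile uses lower interpolation on the
cumulative-weight grid; any consistent definition passes the oracle test,
so this one is pinned for reproducibility. Empty zones fall back to the
global area-weighted percentile, logged. Closing gaps raises every
cultivated yield to `max(current, attainable)` and nothing else. Pixel
biodiversity aggregates as `BD = sum_i p_i (BD_crop p_crop + BD_pv p_pv)`
over the modelled crops; area outside those crops and primary vegetation
is deliberately not renormalized over. Percentage change is
`100 (new - base)/base` (reported so gains are positive; the source's
subtraction wording is ambiguous and this reading matches its reported
signs), with zero-baseline pixels undefined rather than infinite, and
RCAR maps sign-flipped for display only.

**Expansion versus intensification.** Both scenarios raise each pixel's
crop production by the same fraction (default 1%). Expansion adds the
equivalent crop area at the cost of primary vegetation — converted land is
assumed as suitable as existing local farmland, so yields and subsistence
yields stay fixed — and the natural-habitat fraction (hence its
buffer–focal difference) is mechanically recomputed; neighbouring cells'
buffers are not propagated, because each pixel's counterfactual is local.
Intensification raises yield on a sub-share `s` of the crop's area by `g`
with `s(1+g) + (1-s) = 1 + delta`: uniform (`s = 1`), 2%-on-50%,
10%-on-10%, and a restoration variant (10% yield increase on 91.8% of the
crop area, 8.2% returned to primary vegetation; the printed split implies
a production factor of 1.0098, accepted as approximately 1%). Pixels
whose counterfactual exceeds 100% cropland or drives primary vegetation
negative are masked and reported as a percentage. Winners are scored per
metric with RCAR polarity inverted, exact ties reported as their own
class, and area-weighted "intensification better" fractions use the
crop's harvested area as weights.

## The synthetic world

The generator exists so every stage is testable with known ground truth;
the source analysis is observational and provides no generative model, so
the noise model here is a stand-in whose realism is untested by design.
Landscape layers are smoothed Gaussian noise (kernel scale 3 cells by
default) mapped monotonically into each layer's range, with composition
enforced cell by cell: per-crop areas sum to at most the cropland
fraction, cropland plus primary vegetation at most 1, natural habitat at
least primary vegetation. Surveys follow the study/block/site hierarchy
(default 20 studies x 2 blocks x 10 sites; the heavier recovery tests use
50 studies x 20 sites), with sites at the centres of cells cultivating
the focal crop — all covariates are cell-level, so sub-cell coordinates
add nothing. Richness is drawn Poisson with study, block and site
(observation-level) random intercepts (defaults 0.3, 0.2, 0.2 on the log
scale); log_e rescaled abundance and log10 RCAR are drawn Gaussian
(residual sd 0.5) directly on the modelled scale, which makes recovery
tests exact in expectation. Default fixed effects are an intercept with
yield, natural-habitat and land-use effects of realistic magnitude
(e.g. 2.5, -0.25, +0.15, -0.4 for log richness). A single master seed is
split deterministically into per-stage streams (grid, placement,
responses), so every artefact is bit-reproducible.

What passing tests show — and do not show. Parameter recovery (each true
coefficient within two standard errors in at least 90% of 20 replicate
worlds of 50 studies) and structure recovery (backward selection keeping
exactly the one true effect among five candidates) certify the estimator
and selection machinery under the generator's assumptions: Gaussian
random effects, correctly specified mean structures, cell-level
covariates. They do not certify behaviour under the taxonomic and
geographic biases, measurement-unit heterogeneity or spatial
autocorrelation of real survey collations. Note that exact structure
recovery is capped near `(1 - alpha)^4 ~ 0.81` in expectation by the
false-retention rate of stepwise selection itself, so the 90% bar is
demanding at 20 replicates.

## Numerical and size choices

Grids of 30x30 to 40x40 cells and a few hundred sites keep the default
test worlds small enough to iterate on while leaving every composition
inequality and aggregation identity checkable exhaustively; the oracle
tests for the pixel aggregations run on 100x100 grids at a tolerance of
1e-12 against independent per-pixel loops. The matched-production
contract is enforced to 1e-9 relative. Degenerate inputs are signalled,
not silently repaired: all-zero crop areas, zero-abundance studies,
non-positive-definite covariance, non-converged fits (flagged and refused
downstream, never dropped quietly).

Known limitations: grids are abstract equal-area lattices — real-raster
reprojection is out of the tested core (a bilinear resampler is provided
as a utility); no landscape-configuration effects (edge density, patch
size); no temporal dynamics or recovery lags for restored vegetation; the
expansion counterfactual is per-pixel, with no multi-pixel optimization
of where expansion would actually occur. Grid files are plain CSV with a
JSON sidecar carrying layer names and shape, a text format chosen so
grids round-trip exactly and diff cleanly under version control.
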