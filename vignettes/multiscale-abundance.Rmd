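---
title: "Multi-scale hierarchical N-mixture modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale hierarchical N-mixture modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmixscape)
```

## The model

`nmixscape` analyses repeated point counts of a territorial bird (the
motivating system is ring-necked pheasant surveys in an agricultural
landscape) with a binomial-Poisson hierarchical N-mixture model. Site
`i`, nested in management area `k`, holds a latent abundance

$$N_i \sim \text{Poisson}(\lambda_i), \qquad
  \log \lambda_i = \beta_0 + \gamma_{k(i)} + \sum_m \beta_m x_{im},
  \qquad \gamma_k \sim \text{Normal}(0, \sigma^2),$$

and each of the `J` visits records a thinned count

$$y_{ij} \sim \text{Binomial}(N_i, p_{ij}), \qquad
  \text{logit}\, p_{ij} = \alpha_0 + \alpha_t t_{ij} + \alpha_{t^2} t_{ij}^2
  + \alpha_d d_{ij},$$

where `t` is standardized time of day (with a quadratic so detection can
peak mid-morning) and `d` is standardized Julian date. The population is
assumed closed across the visits of a season, so the same `N_i` is
available on every visit; the maximum count over visits is the
model-free abundance index used for validation. All covariates are
standardized (sample SD, `n - 1` denominator, used consistently
everywhere), which puts coefficients on a common scale and is what makes
the per-cover comparison of the two radii meaningful.

Abundance covariates are circular moving-window proportions of six land
cover classes (CRP grassland, other grass, trees, small grains, row
crops, wetlands) at two radii — 1 km, the management scale, and 5 km,
roughly a natal dispersal distance — plus a township-standardized
elevation index and a linear year term. The elevation index subtracts
the mean and divides by the SD of elevation within ~9.66-km square
blocks, turning absolute elevation into local topographic relief; it is
invariant to shifting or positively rescaling the DEM.

## Fitting: marginalized likelihood and the sampler

Rather than sampling the discrete `N_i`, the likelihood marginalizes
them with a truncated sum,

$$L_i = \sum_{N = \max_j y_{ij}}^{K}
  \text{Pois}(N; \lambda_i) \prod_j \text{Bin}(y_{ij}; N, p_{ij}),$$

which is testable against a brute-force oracle and avoids discrete
latent updates. `K` defaults to `max(y) + ceiling(10*sqrt(max(y))) + 50`,
far beyond the Poisson tail; `nmix_total_loglik()` lets a user confirm
that doubling `K` changes the fitted log-likelihood by less than 1e-6.
The exported `site_marginal_loglik()` always evaluates the full sum; the
sampler's internal evaluation stops a term once it falls 45 log-units
below the running maximum *and* is past the mode, a relative error below
double precision. The per-site binomial factor is decomposed as
`C_i(N) + A_i + N B_i` with `C_i(N) = sum_j lchoose(N, y_ij)` cached, so
an abundance-side proposal costs one pass of exponentials per site.

The sampler is adaptive Metropolis-within-Gibbs, written in C++:

* single-parameter random-walk updates for every `beta` and `alpha`,
  per-area updates for the non-centered effects `u_k = gamma_k / sigma`,
  and a random-walk update for `sigma` under its Uniform(0, 10) prior;
* an *interweaved* centered update for `sigma` (holding
  `gamma = sigma u` fixed, so only the prior ratio enters), which
  decouples `sigma` from the `u_k`;
* a likelihood-invariant shift of the intercept against the random
  effects, which removes the `beta_0`–`mean(gamma)` ridge;
* five joint Gaussian proposals per sweep over the concatenated
  `(beta, alpha, u)` vector, with covariance accumulated online (Welford)
  during burn-in, scaled by `2.38^2/d`, mildly shrunk towards its
  diagonal, and globally tuned to a 0.25–0.45 acceptance rate. Landscape
  covariates are strongly inter-correlated (mutually exclusive cover
  classes, overlapping focal windows), the detection and abundance
  intercepts trade off along a `lambda p` ridge, and coefficients of
  between-area covariates trade off against the random effects; the
  joint move carries the mixing along all these directions.

All proposal scales and the joint covariance adapt during burn-in only
and are frozen afterwards, preserving detailed balance for the retained
draws. Chains are seeded `seed + chain - 1` and use R's RNG, so every
fit is exactly reproducible. Priors are diffuse by convention:
coefficients Normal(0, SD 10), `sigma ~ Uniform(0, 10)`; both are
configurable in `model_spec()`.

Convergence is assessed with the Gelman-Rubin statistic per parameter
(`sqrt(((n-1)/n W + B/n)/W)`; below 1.1 read as converged) and fit with
a chi-squared posterior predictive check: at each retained draw the
latent `N_i` is drawn from its truncated conditional, the discrepancy
`sum_ij (y_ij - N_i p_ij)^2 / (N_i p_ij + 0.5)` is computed for the
observed counts and for counts replicated from the same draw, and the
Bayesian p-value is the fraction of draws where the replicated
discrepancy exceeds the observed one (ties count one half). The 0.5 in
the denominator guards division by zero when `N_i p_ij` is tiny.

A fixed detection probability (`fixed_p` in `model_spec()`) supports the
degenerate checks: with `p = 1` the mixture collapses to Poisson
regression (the sampler nudges `p` to `1 - 1e-9` because the
marginalized decomposition needs `p < 1`; the induced log-likelihood
error is of order `1e-9 * sum(y)`).

## Scale selection

Following a hypothesis-testing rather than information-theoretic route
(model-selection criteria are contentious for hierarchical Bayesian
models), two single-scale candidate models are fitted — all six covers
at 1 km, then all six at 5 km, both with linear cover terms only plus
elevation and year — and, per cover type, the radius with the larger
absolute standardized posterior-mean coefficient is retained.
Exact ties default to the landscape (5-km) radius and are flagged. Posterior
SDs are reported next to both candidates so fragile choices are visible,
and `choose_scale_per_cover(override =)` lets the analyst force a radius:
in the worked-example coefficient table shipped with the package the
wetland row (0.21 at 1 km vs −0.22 at 5 km) can only be reproduced
through such a judgment, so the override is a first-class part of the
interface, logged in the decision table. The final mixed-scale model
takes 1-km winners linearly, 5-km winners with linear plus quadratic
terms (the quadratic of the standardized value), always includes
elevation and year, and retains all effects without further pruning.

Cross-scale correlation caps how often the generating radius can be
identified: the two radii of the same cover are correlated at 0.7–0.8 in
the worked example and in our synthetic landscapes, so the package's
recovery tests require the generating radius to win in at least 70% of
cover types, not all of them.

## Spatial prediction and the cubic correction

`linear_predictor_raster()` projects posterior-mean coefficients back
onto raw rasters by standardizing each cell with the stored training
constants; the random intercept enters at its population mean of zero,
and terms without maps (year) are held at their training mean. Because
fitted crop relationships are positive over the sampled range, the
surface extrapolates upward into landscapes far more crop-dominated than
any training site. The biological correction constrains this: for row
crop and small grains in turn, with every other covariate at its
training mean, a cubic term is solved so the prediction at 100% cover is
exactly zero, `c = -eta(1) / z(1)^3`, and `apply_correction()` adds
`c z^3` to the surface. "Prediction equal to zero" is interpreted on the
linear-predictor scale — the SDM is the sum of weighted rasters plus
intercept, and `exp(eta) = 0` is unattainable — which is immaterial for
rank-based evaluation since either reading is a monotone image of the
same surface. The corrected surface equals the fitted one wherever the
crop covariates sit at their training means, so the correction chiefly
affects extrapolated cells.

`classify_equal_area()` bins a surface into ten classes of equal cell
count (class 10 = highest), breaking ties by value order then cell index
so heavily tied surfaces still partition evenly.

## Validation and diagnostics

Independent transects (10 lines of 15 points ~5 km apart in the full
design) are never pooled with training data. Observed abundance is the
per-site maximum count over three visits; predicted abundance is the
surface extracted at the site cell. The report contains Spearman's rank
correlation (average ranks on ties), the RMSE between the two vectors
after each is z-scored with its own mean and sample SD (hence invariant
to positive affine maps of the predictions), and an OLS calibration line
of standardized observed on standardized predicted values with 95%
confidence limits. Residual diagnostics use `observed max count minus
N_mean * max_j p_hat_ij` — the fitted expectation of the best visit — a
definition chosen for transparency since nothing canonical exists for
the max-count index: a normal QQ plot at plotting positions
`(i - 0.5)/n`, and a Moran's I correlogram over half-open distance bands
`(low, high]` with binary weights (classical, non-row-standardized
form), computed for the raw max counts and for the residuals; the
contrast shows how much spatial autocorrelation the area random
intercept absorbed.

## The synthetic-data generator

The generator exists so every stage can be tested against known truth;
its defaults are the study conditions of the motivating field design:
45 areas x 9 points with >= 300 m spacing x 3 visits (405 sites, 1,215
site-visits), 10 validation transects of 15 points at 5 km, 30-m cover
rasters in six mutually exclusive classes, survey times uniform on
[sunrise - 15 min, 10:00] with sunrise fixed at 06:00, Julian dates
uniform on [105, 212], years 2010-2012. The default true coefficients
mirror the worked-example mixed-scale estimates (e.g. intercept 3.07,
trees at 5 km -0.55, row crop at 5 km 0.51), with a random-intercept SD
of 0.3 and a detection model peaking mid-window; where the field
protocol implies no distribution (times, dates) the uniform choice is an
assumption, stated here once.

Cover maps are built by thresholding independent smoothed Gaussian
random fields; classes claim cells in the order of the proportions
vector, each taking its target share of the not-yet-claimed cells where
its field is highest, so realized proportions match targets to within
one cell and classes are exclusive by construction. The DEM is a smooth
field plus fine-scale noise so every township block has positive
variance. The generator emulates the *stochastic structure* the model
assumes — it makes no attempt at real geography, roads, patch-size
distributions, or classification error, and the 500-m survey radius is
represented only through site spacing, not a distance-detection
function. Passing recovery tests therefore demonstrates correctness of
the machinery under the model's own assumptions, not robustness to the
ways real land-cover data violate them.

Survey areas and transects are inset from the landscape edge by the
largest focal radius so every site has a complete covariate window;
without the inset, truncated edge windows produce standardized
covariates tens of SDs outside the training range, and a positive
quadratic term then makes extrapolated predictions explode — the same
runaway behaviour the cubic correction addresses, but as an artifact of
the synthetic frame rather than of crop dominance.

## Problem sizes and numerical choices at desk scale

The full-scale MCMC default follows the motivating analysis: 3 chains x
35,000 iterations, burn-in 5,000, thinning 50. For tests, examples, and
the acceptance script the package uses its smoke preset (3 x 3,000,
burn-in 1,500, thin 5; the end-to-end script doubles this to 3 x 6,000)
and a 600 x 600-cell landscape at 150-m cells with 20 areas x 9 sites —
sizes chosen so a complete run takes about a minute on one core while
keeping every stage statistically meaningful (posterior SDs ~0.05 on
standardized coefficients, 150 validation sites). Parameter-recovery
checks use 270 sites in 30 areas with |beta| <= 0.6 and sigma = 0.3.

Other numerical conventions, stated once: focal windows include cells
whose centers lie within the radius (inclusive boundary), shrink at the
raster edge, and are computed by FFT convolution rounded to integer
counts, making them bit-equal to the brute-force window mean; cells are
half-open `[x0, x0 + w)` so a point on a shared edge belongs to the
east/north cell; township blocks anchor at the raster origin and a
trailing sliver narrower than two cells merges into its neighbour; a
flat block yields elevation index 0 with a warning; the collinearity
threshold `|rho| >= 0.6` is inclusive and the screen only reports pairs
(in the worked example both members of a flagged 1-km pair appear in the
final model, so elimination is left to the analyst); posterior quantiles
use the type-7 convention; and empty-band Moran's I entries are reported
as missing rather than zero.

## Known limitations

* The sampler is a random-walk scheme; posteriors with hundreds of
  highly collinear covariates would mix slowly. The adaptive joint move
  handles the designs in scope (~15 coefficients, ~45 areas).
* Predictions are relative-abundance surfaces, meaningful up to monotone
  transformation; absolute density would additionally require the survey
  radius and a detection function, both out of scope.
* The equal-cell decile classification equates cells with area, which is
  exact only for projected rasters with square cells, the only raster
  type the package represents.
* Moran's I permutation envelopes are only practical for the point-set
  sizes used here (hundreds); the correlogram otherwise reports the
  normal approximation.
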