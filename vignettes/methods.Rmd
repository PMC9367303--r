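---
title: "Methods: distance sampling and ensemble habitat models in porpoisetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance sampling and ensemble habitat models in porpoisetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porpoisetools)
```

`porpoisetools` implements the two computational engines of a coastal
harbour-porpoise monitoring analysis — conventional line-transect distance
sampling (CDS) for density and abundance, and an ensemble-of-small-models
(ESM) MaxEnt analysis for habitat suitability — together with a synthetic
survey generator with known truth, so that every stage can be validated by
parameter recovery rather than by visual inspection.

## 1. Conventional distance sampling

### Model

An aerial survey records, for each detected porpoise group, the
perpendicular distance $y$ from the trackline (derived from the clinometer
declination $\theta$ and altitude $h$ as $y = h / \tan\theta$) and the group
size $s$. Detection probability declines with distance according to a
detection function $g(y)$ with $g(0) = 1$ by convention. Given effort $L$
(total transect length), truncation distance $W$, and the effective strip
width $\mu = \int_0^W g(y)\,dy$, the density estimator with availability
correction $g(0)$-true $= g_0$ is

$$\hat D = \frac{n\,\hat E[s]}{2 L \hat\mu\, g_0}, \qquad \hat N = \hat D A.$$

The conditional likelihood of the distances is $\prod_i g(y_i)/\mu$.
`fit_detection_function()` maximizes it for three keys (uniform,
half-normal, hazard-rate) with optional series adjustments (cosine orders
1–3 for the uniform key, 2–3 for half-normal; Hermite 4, 6; simple
polynomial 4, 6 for hazard-rate). Adjustment terms are added greedily while
AIC improves, up to three terms. `fit_candidate_models()` fits the four
conventional key/adjustment combinations and `select_model()` picks the
lowest AIC, breaking exact ties by fewer parameters and then by key order.

### Numerical choices

* The ESW is computed by adaptive quadrature (`integrate`, relative
  tolerance $10^{-9}$); for the pure half-normal key it agrees with the
  closed form $\sigma\sqrt{\pi/2}\,\mathrm{erf}(W/\sigma\sqrt2)$, which the
  test suite checks to $10^{-4}$.
* One-parameter fits use Brent's method on $\log\sigma$; multi-parameter
  fits use Nelder–Mead. Negativity of the adjusted series on $[0, W]$ is
  penalized during optimization; if the final fit still dips below zero,
  terms are dropped and the model flagged (`truncated_negative`).
* Monotonicity of $g$ is checked, not constrained; non-monotone fits are
  flagged in the returned object.
* Degenerate inputs (all distances at zero) drive $\hat\sigma$ to the
  optimization floor; such fits carry `degenerate = TRUE`.
* Default truncation is the maximum observed distance; $W$ is always
  configurable.
* Internal units are km and km$^2$; report tables round densities to three
  decimals and abundances to the nearest integer.

### Group size, pooling and uncertainty

Larger groups are easier to see far from the line, so the observed mean
group size is biased up. `expected_group_size()` regresses $\ln s_i$ on
$\hat g(y_i)$; when the slope is significant at $\alpha = 0.15$
(two-sided), the corrected mean is the prediction at $g = 1$ with the
log-normal back-transform $\exp(\hat a + \hat b + \hat\sigma^2_{res}/2)$,
otherwise the observed mean is used. The correction's CV uses the standard
error of the log-scale prediction (delta method); the observed mean's CV is
$\mathrm{sd}(s)/(\bar s\sqrt n)$.

Stratum estimates pool a single global detection function (as is standard
when per-stratum sighting counts are small); the overall density is the
effort-weighted mean $\sum_i D_i L_i / \sum_i L_i$ — this pooling rule also
reproduces the arithmetic of multi-year survey tables in the validation
suite. Because annual strata resurvey the same region, the combined
abundance multiplies the pooled density by the region's area, not by the
sum of stratum areas.

CVs and 95% confidence intervals come from a nonparametric bootstrap
(`bootstrap_estimates()`, default $B = 999$) that resamples transects with
replacement within strata, refits the detection function in every replicate
with the *selected* key/adjustment structure (greedy term selection is not
re-run inside replicates, which keeps $B = 999$ tractable and avoids
model-selection noise in the intervals), re-runs the size-bias regression
and recomputes all estimates. Replicates with no sightings contribute a
density of zero. Intervals are percentile (2.5th/97.5th).

The availability correction is a single multiplicative constant: an animal
on the trackline is detectable only with probability $g_0 < 1$ (diving
species). `apply_g0()` divides density and abundance by $g_0$ and leaves
the CV unchanged. The default $g_0 = 0.364$ is the published aerial-survey
value for harbour porpoise in good sighting conditions.

## 2. Ensembles of small models with MaxEnt

With few presences (tens per year), a single model with many predictors
overfits. The ESM strategy fits *every bivariate model* — one per
unordered pair of the $k$ eco-geographical variables (EGVs), $C(k,2)$
pairs — repeatedly over background replicates and cross-validation splits,
scores each run by Somers' $D = 2\,\mathrm{AUC} - 1$ on held-out data, and
combines runs with $D \ge 0.5$ into a weighted average with weights
$D_i/\sum_j D_j$.

### The MaxEnt member model

`fit_maxent()` fits the presence/background model as a class-weighted
penalized binomial likelihood with linear + quadratic features of the two
EGVs: presences and background each carry total weight one half
(prevalence 0.5). Features are standardized, so the L1 penalty scales with
each feature's spread; the default penalty is $0.05/\sqrt{n_{pres}}$ on the
mean-scaled likelihood, a mild shrinkage comparable to MaxEnt's
small-sample defaults (the multiplier is exposed as `reg_multiplier`, and
`reg_multiplier = 0` gives the exact unpenalized optimum, which the test
suite cross-checks against an independent optimizer and against glmnet).
Optimization is by FISTA proximal gradient with an exact Lipschitz constant
from the weighted Gram matrix; product features are excluded because each
member model has only two predictors. Predictions use the complementary
log-log transform with entropy normalization over the background (a
logistic output is available); predictors are clamped to the training range
before evaluation, so extrapolated cells predict like boundary cells.

### Evaluation and summaries

* Somers' D compares held-out presences against the held-out background of
  the same 80/20 split, with ties counted one half.
* The Continuous Boyce Index (`boyce_index()`) sweeps a moving window
  (width 10% of the HSI range, 101 midpoints) across the suitability range,
  forms the predicted-to-expected presence ratio per window, removes
  consecutive duplicate ratios produced by overlapping windows, and reports
  the Spearman correlation of the ratio with the window midpoint. A
  constant map returns 0 with a `degenerate` attribute.
* Variable contributions average Somers' D over **all** bivariate runs
  containing the variable (the full run pool, not only runs retained for
  prediction — retention censoring at the 0.5 threshold would otherwise
  discard most of the discriminative signal) and normalize to percentages
  summing to 100. Negative mean scores are clamped at zero before
  normalizing.
* Multi-year maps are summarized cell-wise by the mean and the coefficient
  of variation (sample SD / mean); cells with mean zero get no-data CV.

The retention threshold is applied as "keep $D \ge 0.5$", and if no run
clears it, `build_ensemble()` fails loudly with "no skillful models"
rather than silently returning a random-quality map.

## 3. The synthetic-data generator

`make_environment()` builds the five EGVs (bathymetry, slope, SST,
chlorophyll-a, ammonium) on a 1-km planar grid with a straight coastline on
the low-x edge: depth increases offshore, chlorophyll is negatively coupled
to SST by construction (an upwelling-like pattern), ammonium decays
offshore, and all fields carry spectrally smoothed Gaussian texture with a
15 km correlation length (the texture scale is a simulation choice; the
sources the generator emulates do not constrain it). Slope is derived from
bathymetry with Horn's 3×3 gradient — the same routine exposed to users in
`slope_from_bathymetry()`.

`true_suitability()` encodes the simulation truth as a logistic function of
the raw layers, monotone increasing in chlorophyll and decreasing in SST
and depth under the default signs. `place_groups()` realizes an
inhomogeneous Poisson point process with intensity proportional to
suitability and i.i.d. zero-truncated Poisson group sizes; the default rate
$\lambda = 0.70$ gives mean group size $\lambda/(1 - e^{-\lambda}) =
1.390$, matching the observed scale for this species. `make_transects()`
lays parallel lines perpendicular to the coast, 20 nm long and spaced
10 nm, with the first line offset half a spacing from the domain edge
(equal coverage probability). `simulate_survey()` records each group within
the truncation strip with probability $g_0\,g(y)$; availability bias is a
single Bernoulli thinning with probability $g_0$, constant in distance —
matching the multiplicative correction applied in the estimator. The
half-normal key ($\sigma = 0.12$ km, $W = 0.3$ km) is the simulator default;
hazard-rate truth is available for misspecification experiments.

What the generator does *not* emulate: real coastline geometry, tides and
upwelling dynamics, temporal animal movement, responsive movement to the
aircraft, or measurement error in angles and group sizes. Passing tests
therefore demonstrate the estimators' internal correctness and calibration
under the stated models, not robustness to all field conditions.

### True density in recovery experiments

The spatial distribution of the true population is a simulation choice
(suitability-proportional intensity); nothing in the reproduced analysis
constrains it. `recovery_experiment()` therefore uses a *flat* suitability
so the true density is known exactly: $D = \text{intensity} \times
\lambda/(1 - e^{-\lambda})$ individuals per km$^2$. Each replicate pools
five independent passes over a 40-transect design — the multi-year pooling
that a real monitoring programme uses to fit a single global detection
function — giving roughly 55 sightings per replicate at the default group
density of 0.07 groups km$^{-2}$, the scale implied by the published
estimates for this population.

## 4. Problem sizes used by the validation suite

The test and acceptance runs scale the ESM down from the full published
protocol (10 background datasets of 10,000 points × 10 splits) to sizes
that exercise the same code paths with adequate power: background sets of
400–2,000 points, 1–3 background replicates, and 3–8 cross-validation
splits; the full protocol remains the default of `run_esm()`'s
caller-facing arguments. Parameter-recovery uses 200 simulated surveys
(bias), 100 surveys × 199 bootstrap replicates (CI coverage), and 20 seeded
end-to-end ESM runs (chlorophyll power). These sizes are the package's own
validation design.

## 5. Design decisions that were genuinely open

* **Pooling rule for the overall estimate** — effort-weighted mean of
  stratum densities; chosen because it is the standard design-based rule
  and reproduces the published multi-year table arithmetic.
* **Bootstrap structure** — refit detection function per replicate with
  fixed structure; percentile intervals.
* **Contribution convention** — percentages summing to 100 over the full
  run pool (see §2); the alternative "rescale by the largest" convention is
  not implemented.
* **Regularization scale** — see §2; heavy penalties at these sample sizes
  shrink every member model to the constant and make ensembles impossible,
  so the default is deliberately mild.
* **Somers' D evaluation background** — the held-out 20% of the background
  of the same split (the natural pairing; the alternative of scoring
  against the full background changes little but breaks the train/test
  symmetry).
* **Screening rule** — pairwise Pearson over sea cells,
  strictly-greater-than 0.7 on the absolute value, iterative removal of the
  lower-priority member, retained set forced constant across years.
* **Power experiment truth** — chlorophyll-dominant with mild negative SST
  and depth effects, on a 60 × 300 km domain; on smaller domains the
  15 km-correlated fields provide too few independent habitat patches to
  separate correlated predictors reliably.

## 6. Known limitations

* No covariate (MCDS) detection functions and no double-platform
  estimation of $g_0$: the correction is an imported constant, and its
  uncertainty is not propagated.
* The ESM uses MaxEnt members only; no GLM/GAM/forest members and no
  spatial-block cross-validation.
* Rasters are plain matrices on a planar km grid; no projections and no
  geographic I/O beyond the ASCII-grid dialect.
* IDW interpolation and distance-to-coast use exact brute-force
  neighbourhoods, which is fine at the package's intended grid sizes
  (hundreds × hundreds of cells) but not for continental grids.
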