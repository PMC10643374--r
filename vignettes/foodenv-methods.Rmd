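---
title: "Methods: activity-based and location-based food environment indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-based and location-based food environment indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodenv)
```

## The two indices

Location-based measures of the retail food environment summarize what is
*near* a census tract; activity-based measures summarize where its residents
*actually go*. `foodenv` implements both on the 0-100 scale.

The **modified retail food environment index (mRFEI)** for a tract is

$$\mathrm{mRFEI} = 100 \cdot
  \frac{\#\,\text{healthy retailers}}
       {\#\,\text{healthy retailers} + \#\,\text{less healthy retailers}},$$

counting retailers located inside the tract polygon or within half a mile of
its boundary. Retailer classes follow 2007 NAICS codes with employee-size
rules: supermarkets and larger grocery stores (445110 with at least 10
employees), warehouse clubs (452910) and fruit and vegetable markets (445230)
are healthy; small grocery stores (445110, three or fewer employees),
limited-service restaurants (722211) and convenience stores (445120) are less
healthy.

The **retail food activity index (RFAI)** replaces retailer counts with
resident visit counts from aggregated origin-destination mobility flows:

$$\mathrm{RFAI} = 100 \cdot
  \frac{\#\,\text{visits to healthy retailers}}
       {\#\,\text{visits to healthy retailers} +
        \#\,\text{visits to less healthy retailers}},$$

with classes from 2017 NAICS codes: 445110 (regardless of employment size),
452311 and 445230 healthy; 445120 and 722513 less healthy. Visits to POIs
outside these categories are ignored. A third, *alternative location index*
applies the mRFEI formula with the activity scheme's classes, isolating the
location-vs-activity contrast from the vintage/employee-rule contrast.

Two deliberate conventions:

* **Missing, not zero.** A tract with no qualified visits (RFAI) or no
  qualified retailers in scope (mRFEI) gets a missing index. Zero is a
  meaningful value ("all less healthy"), so conflating the two would bias
  associations downward. Missing counts are logged, and models use listwise
  deletion with reported drop counts.
* **The employee-size gap.** The location scheme defines 445110 stores with
  at least 10 employees as healthy and three or fewer as less healthy; stores
  with 4-9 employees fall between the stated rules and are excluded from both
  numerator and denominator, as are 445110 stores with an unknown employee
  count. Exclusion is conservative and avoids silent misclassification; the
  counts are reported. The NAICS vintage crosswalk is limited to the two code
  pairs that actually renumber (452910/452311, 722211/722513) and is not
  extrapolated.

## Geometry

Tract polygons arrive as GeoJSON or shapefile in WGS84 lon/lat, or (for
synthetic studies) in planar mile coordinates flagged by a dataset-level
`planar_miles` marker. Distances between tract centroids and POIs use the
haversine great-circle formula on a sphere of radius 3958.8 miles in lon/lat
mode and plain Euclidean distance in planar mode. The half-mile scope test
(inside the polygon, or within the radius of its boundary) re-projects the
tract and nearby POIs to a local azimuthal-equidistant frame centered on the
tract centroid, then tests planar point-to-polygon distance; at half-mile
scale the projection error is negligible, and the same routine serves both
the mRFEI retailer scope and the within-half-mile visit share so the two are
internally consistent. Self-intersecting rings are either rejected or
repaired by splitting at their crossing points into simple loops (even-odd
interiors), under a caller-chosen flag; repairs are reported.

Distance bands are half-open and lower-inclusive - [0,1), [1,5), [5,10),
[10,20), [20, infinity) miles - so the printed bands partition exactly; a
distance of exactly 1.0 falls in the second band. The per-tract median
travel distance is visit-weighted (each visit counts once, not each
aggregated flow record) using the lower weighted median: the smallest value
whose cumulative weight reaches half the total. Band shares can be
aggregated across tracts either as per-tract means (each tract counts once,
with a between-tract SD) or pooled over all visits; both are exposed because
aggregate summaries of this kind are ambiguous between the two readings.

## Association models

The modeling battery is ordinary least squares with an intercept, classical
standard errors, and two-sided 95% t-intervals. The fully adjusted
index-disease specification contains 15 covariates: the four social
vulnerability theme percentiles (theme 3 - minority status - optionally
replaced by predominant-group indicators at an inclusive 50% population
threshold), food-desert and urban flags, log population density, log
per-capita food retailer visits (a mobility-coverage control), the
percentages female, minority, low income, less than high school, under 5 or
over 64, median family income, and the log count of food retailers. Natural
logs are used throughout; rows with nonpositive arguments are dropped and
counted rather than offset. No multiple-testing adjustment is applied; CIs
are reported model by model.

Effects on the index scale are reported per **interquartile increase**
(25th to 75th percentile of the analysis sample's exposure, type-7
linear-interpolation quantiles). For log outcomes, coefficients convert to
percent changes via $100(e^\beta - 1)$, and log-log coefficients to
per-doubling effects via $100(2^\beta - 1)$.

The sensitivity stack:

* **Median regression** (check-loss at the 0.5 quantile) is fitted by
  iteratively reweighted least squares for the least-absolute-deviations
  objective, polished with a Nelder-Mead pass over the nondifferentiable
  loss; confidence intervals come from a fixed-seed case-resampling
  bootstrap (500 replicates by default). The bootstrap was chosen because it
  is estimator-agnostic; rank-inversion intervals would tie the interval to
  asymptotics the small county-level samples may not support.
* **Generalized additive models** use a penalized thin-plate spline for the
  exposure (mgcv, REML smoothing by default, GCV available) with linear
  covariates, reporting the smooth's effective degrees of freedom and the
  partial-effect curve on a 100-point exposure grid. An effective df near 1
  indicates an essentially linear exposure-response.
* **County aggregation** pools flow-derived counts (a county's RFAI is the
  pooled healthy-visit share, identical to recomputing from pooled flows),
  population-weights covariate and prevalence means, and sums counts. A
  retailer within half a mile of two tracts' boundaries contributes to both
  tracts' location-index counts, so pooled county retailer counts inherit
  that double counting; this is documented rather than corrected, since the
  tract-level definition itself is scope-based rather than partition-based.
* **The spatial error model** $y = X\beta + u$, $u = \lambda W u +
  \varepsilon$ is estimated by concentrated maximum likelihood: for a
  candidate $\lambda$ the filtered data $(I-\lambda W)y$, $(I-\lambda W)X$
  give $\hat\beta(\lambda)$ and $\hat\sigma^2(\lambda)$ in closed form, and
  the log-determinant uses the precomputed eigenvalues of $W$. Coefficient
  standard errors are conditional on the estimated $\lambda$. Weight
  matrices are row-standardized contiguity (queen or rook) matrices; an
  estimate at the feasibility boundary raises an error instead of returning
  a spurious optimum.
* **Stratified fits** repeat a specification within predominant-group
  strata plus their complement, skipping (with a warning) strata too small
  for the design.

## The synthetic study generator

Real inputs of this kind - proprietary aggregated GPS flows joined to
surveillance and census products - cannot ship with a package, so `foodenv`
generates complete synthetic studies with known ground truth. The generator
emulates the statistical *structure* of such data, not U.S. geography:

* **Region.** A grid (default 30 x 30) of one-square-mile tracts in planar
  coordinates. Populations are log-normal (meanlog 8.2, sdlog 0.5; median
  about 3,600, matching the order of a typical census tract). Four SVI theme
  percentiles are rank-transformed Gaussians sharing a latent deprivation
  factor (correlation 0.7). Racial/ethnic shares come from a
  deprivation-tilted Dirichlet so predominant tracts of each group occur.
  Tracts are urban above 2,500 persons per square mile, a threshold chosen
  to leave roughly a fifth of tracts non-urban under the population
  distribution. The food-desert flag follows a low-income, low-access rule:
  bottom-40% family income and no supermarket/grocery store within 0.5
  miles of the centroid (10 miles if non-urban).
* **Retailers.** Per-tract Poisson counts with intensity proportional to the
  square root of density (about 1,500 POIs at the default size), categories
  drawn from a national-order mix over the five NAICS categories tilted
  toward convenience stores and limited-service restaurants in deprived
  tracts, uniform locations, and employee counts for 445110 stores spanning
  all three size classes so both classification schemes are exercised.
* **Flows.** A gravity destination-choice model: tract $i$ sends
  $\mathrm{Poisson}(\text{population}_i \times \text{visits per capita})$
  visits (default rate 20), distributed multinomially with probability
  proportional to $a_j \, e^{-d_{ij}/\delta} \, e^{(\theta^\top x_i + u_i)
  \mathbf{1}[j\ \text{healthy}]}$: POI attractiveness $a_j$ (log-normal
  around category means), exponential distance decay ($\delta = 3$ miles -
  bounded at zero distance and yielding closed-form band expectations,
  unlike a power law), a covariate-linked healthy-food preference
  ($\theta$ on the socioeconomic vulnerability percentile), and a
  tract-level random taste $u_i \sim N(0, 0.5^2)$. The taste term encodes
  the behavioral heterogeneity that sociodemographics do not explain - the
  substantive reason activity-based indices diverge from location-based
  ones - and it gives the true index variation beyond its covariate
  predictors, without which any regression on the observed index would be
  dominated by errors-in-variables attenuation. The **true RFAI** is
  computed exactly from the choice probabilities (not from sampled visits),
  so sampling attenuation is measurable: the observed index is a binomial
  estimate of the true one with known per-tract denominator.
* **Outcomes.** Disease prevalence is affine in the true index plus
  covariate effects and Gaussian noise (SD 2 percentage points), clipped to
  [0,100] with clip events counted. The planted obesity coefficient is
  -0.025 prevalence points per index unit, about -0.6 points per
  interquartile increase - the order of magnitude a tract-level ecological
  association of this kind plausibly takes.

What passing tests on this generator do *not* show: realistic U.S. road or
settlement geography, device-sampling bias, home-location inference error,
or small-area estimation error in the prevalence surface. The generator's
conclusions are about the pipeline's correctness, not about any real
population.

## Numerical choices and degenerate inputs

* Earth radius fixed at 3958.8 miles and recorded in the run configuration.
* Weighted medians use the lower-median convention; quantiles are type 7.
* Duplicate (origin, POI, year) flow rows are summed with a logged count;
  empty cells are the only missing-value encoding in CSVs ("NA"/"NaN"
  strings are rejected).
* All-zero weights, fewer than 3 complete index pairs, constant exposures,
  and rank-deficient designs raise typed errors naming the offending input
  rather than returning silent defaults; the pipeline additionally drops
  covariates that are constant in a given study (with a log line) since a
  constant column is uninformative and would otherwise abort the fit.
* Every random stage derives its stream from the scenario seed, so a study
  bundle, and the entire pipeline report derived from it, is bitwise
  reproducible.

## Problem sizes used by the test suite

Unit and property tests run on small constructed instances (single tracts to
10-tract enumerated fixtures; 200-1,000 randomized oracle cases per
statistic). Recovery and null-coverage checks use 100 replicates of the
default 30 x 30 scenario; simulator-fidelity checks use about a million
sampled visits on a 6 x 6 region; the spatial-error recovery uses a 20 x 20
lattice. These sizes make the whole suite run in a few minutes on one core
while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Shapefile support covers the polygon shape type only, which suffices for
  tract boundary files.
* The spatial-error standard errors for the regression coefficients are
  conditional on the estimated spatial parameter; a full information matrix
  would widen them slightly.
* Location-index scope counts retailers once per tract in scope, so county
  pooling double counts boundary retailers (see above).
* The Pearson correlation is used for index agreement; with the indices'
  skewed distributions a rank correlation can differ noticeably.
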