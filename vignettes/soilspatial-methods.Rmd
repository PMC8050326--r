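---
title: "Methods behind soilspatial: variography, kriging and the two-region battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind soilspatial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilspatial)
```

## The problem

Field-scale surveys of soil CO₂ efflux (FCO₂) and companion soil
attributes are usually collected on a regular grid — here the reference
layout is a 90 × 90 m grid of 100 points at 10 m spacing, sampled after
sugarcane field reform. Classical summaries (mean, CV) treat the
attribute as spatially unstructured; geostatistics instead models the
spatial dependence explicitly, interpolates maps by kriging, and lets
contrasting regions of the map be compared with a multivariate battery.
This vignette documents the modeling choices, parameter conventions and
numerical behavior of each stage.

## Variography

### Estimator

`empirical_variogram()` implements the classical Matheron estimator
under the intrinsic hypothesis,
$$\hat\gamma(h) = \frac{1}{2N(h)} \sum_{i=1}^{N(h)}
  \left[z(x_i + h) - z(x_i)\right]^2,$$
over half-open lag bins centered at multiples of the bin width. No
robust variant is offered: the estimator itself is part of the method
being packaged, and its output is checked bin-by-bin against brute-force
pair enumeration in the test suite.

Defaults, chosen where the workflow leaves them open:

* **bin width** — the declared grid spacing (10 m for the reference
  grid), the natural resolution of a regular survey; otherwise the
  minimum pairwise distance;
* **maximum lag** — half the maximum pairwise distance. Beyond that,
  pair counts collapse and the estimator is dominated by edge pairs;
* the reported `dist` per bin is the mean pair separation within the
  bin (not the nominal center), which removes most of the binning bias
  when fitting; the nominal center is retained alongside.

### Model curves and the practical-range convention

Three permissible isotropic models are provided (nugget $C_0$, partial
sill $C_1$, range $a$): spherical, exponential and gaussian, with
$\gamma(0) = 0$ and the nugget as a jump at $0^+$. The exponential and
gaussian kinds are parameterized by their *practical range*:
$\gamma(a) = C_0 + 0.95\,C_1$ holds exactly (rate $\log 20 / a$, of
which the commonly quoted factor 3 is the rounding). This makes a fitted
$a$ comparable across model kinds — important because the spatial
dependence index consumes the range directly.

### Fitting

`fit_variogram()` minimizes the weighted sum of squared residuals over
the bins with Levenberg–Marquardt (`minpack.lm::nls.lm`) under box
constraints $C_0, C_1 \ge 0$, $a > 0$. Default weights are the pair
counts $N(h)$; `equal` and Cressie-style $N(h)/\gamma_{model}^2$
weights (iterated three times) are options. Starting values: nugget
from the first bin, sill from the sample variance, range from the
smallest lag reaching 95% of the sill start.

Two numerical guards matter in practice:

* **Range upper bound 1.5 × the sampled lag span.** A near-flat
  empirical variogram can otherwise be fitted by an arbitrarily long
  range with a compensating partial sill — structure the binned data
  cannot support.
* **Identifiability collapse.** When the optimizer returns a range at or
  below the first sampled lag, the curve is flat over every bin, so only
  $C_0 + C_1$ is identified; the fit is collapsed to a pure nugget.
  Without this rule a white-noise field can be reported with a
  substantial spurious "structured" share.

Reported diagnostics: weighted SSR, unweighted $R^2$ against the
bin-mean baseline, and (when the dataset is supplied) the leave-one-out
kriging RMSE in attribute units. `select_model()` ranks candidates by
ascending SSR, breaking ties by descending $R^2$, then ascending CV
RMSE — a deterministic ordering.

### Spatial dependence index

`spatial_dependence_index()` classifies dependence as weak, moderate or
strong from
$$SDI\% = MF \cdot \frac{C_1}{C_0+C_1} \cdot
  \frac{\min(a, 0.5\,MD)}{0.5\,MD} \cdot 100,$$
where $MD$ is the maximum sampling distance (the grid diagonal,
127.28 m, for the reference grid). Model factors (0.375 spherical,
0.317 exponential, 0.504 gaussian) and thresholds (weak ≤ 7 < moderate
≤ 15 < strong) are configuration, not hard-coded: the published index
this follows is defined in literature not reprinted with the reference
survey, so the defaults were fixed by requiring that all 24 packaged
survey rows reproduce their printed class labels — which they do,
including the borderline rows (P at 15.2%, AFPS at 14.7%, V at 6.9%,
Ca at 7.3%). The index depends only on $C_1/(C_0+C_1)$ and $a$, so it
is invariant to attribute unit rescaling; a pure-nugget model is
defined to have SDI 0 and class weak.

Attributes flagged as log-transformed in the packaged variogram table
are analyzed on the natural-log scale (variography and kriging), and
the flag is recorded on the model.

## Ordinary kriging

`krige()` solves the semivariance form of the OK system: the
sample-to-sample semivariance matrix with zeros on the diagonal,
bordered by the unbiasedness row of ones, with a Lagrange multiplier.
The zero diagonal (γ(0) = 0) means the predictor honors the data
exactly even in the presence of a nugget — the behavior wanted for map
construction from a single-visit survey. Kriging variance
$\sum_i \lambda_i \gamma(x_i, x_0) + \mu$ is clamped at 0 against
roundoff (floor tolerance 1e-9 in the invariants).

The neighborhood is global: with about a hundred samples a dense
101 × 101 solve shared across all raster cells is both exact and fast,
so no search neighborhood is needed. Duplicate sample coordinates make
the system singular and are reported by row before solving.
`krige_map()` predicts cell centers on a raster whose default origin is
half a cell below the data minimum, so whole-meter sample locations fall
on cell centers; 1 m cells by default. Closed-form behaviors — single
sample ⇒ weight 1; pure nugget ⇒ equal weights and the arithmetic mean;
exactness and zero variance at data points; translation invariance —
are all asserted in the suite against an independently coded dense
solve.

Log-flagged attributes are kriged on the log scale and mapped on that
scale; a naive exponential back-transform is biased and is deliberately
not applied silently (the pipeline exponentiates only for region-band
comparison, where the bands are data-scale constants).

## Derived quantities

`derive_attributes()` implements the standard conversions: TOC =
SOM/1.724; Cstock = TOC · Ds · E/10 (Mg ha⁻¹, depth E = 20 cm default);
daily C–CO₂ = FCO₂ · 1e-6 · 12 · 86400 · 0.01 Mg C ha⁻¹ d⁻¹ (carbon
mass, 12 g mol⁻¹, not CO₂ mass — the decay constant k = C–CO₂/Cstock
relates emitted *carbon* to stored carbon); Macro = TPV − Micro;
AFPS = TPV − Ms. SOM reported in g dm⁻³ is treated as g kg⁻¹-equivalent
after the 1.724 conversion, matching how such surveys apply the stock
equation in practice (the packaged summary means are mutually consistent
under this reading). k is computed per record (mean of ratios, not ratio
of means). Degenerate inputs are errors, not NaNs: zero stock with
nonzero flux, negative pore differences, CV at zero mean.

`describe()` uses the small-sample-adjusted moment conventions (G₁ and
excess-kurtosis G₂, normal = 0) and classifies CV by Warrick–Nielsen
thresholds with the boundary values 12 and 24 assigned to "moderate"
(closed interval).

## The two-region battery

* **Student's t** is the pooled-variance form by default, as named in
  two-region survey reporting; Welch is available. Zero pooled variance
  with equal means yields t = 0, p = 1; with unequal means the
  difference is certain under the model (p = 0). No multiple-testing
  correction is applied by default across the nine microbiological
  variables — univariate reporting practice for such comparisons — but
  any `p.adjust` method can be switched on.
* **Hotelling's T²** uses the pooled covariance with
  $F = T^2 (n_1+n_2-p-1)/((n_1+n_2-2)p)$. Its algebraic identities
  (T² = t² at p = 1; affine invariance) are asserted numerically.
* **Ward clustering** uses the classic minimum-variance objective with
  heights on the distance scale (`hclust` method `ward.D2`; the
  squared-height variant is available as an option). The first merge of
  two singletons therefore sits at their Euclidean distance. Heights
  are validated against an exhaustive merge-cost implementation for
  small n.
* **PCA** is computed on the *correlation* matrix by default, although
  covariance-based PCA is selectable: the Kaiser eigenvalue-1 retention
  rule and the |loading| ≥ 0.70 interpretation rule both presuppose
  standardized variables, so applying them to covariance eigenvalues
  would be incoherent. Loadings are variable–component correlations
  (eigenvector × √eigenvalue); component signs are fixed so the
  dominant loading is positive.
* **Region delineation** assigns kriged cells to R1/R2 by inclusive
  value bands (defaults 2.9–4.2 and 1.9–2.7 µmol m⁻² s⁻¹); cells in
  the gap or outside both bands stay unassigned rather than being
  forced into a region.

## The synthetic-data generator

`simulate_grf()` draws Gaussian fields by exact Cholesky factorization
of the assembled covariance $C(h) = (C_0+C_1) - \gamma(h)$ with the
full sill on the diagonal (the nugget is white noise at the grid
points). Exact factorization is deliberate: survey-sized grids make
spectral or low-rank approximations pointless, and a non-positive-
definite assembly is an explicit error naming the parameters.

`simulate_survey()` emulates the reference survey: the packaged tables
supply each attribute's target mean and variogram; FCO₂ acts as the
driver field and SOM, macroporosity, AFPS and silt are generated with
positive correlation to it (0.6–0.7), reflecting the map co-variation
such surveys report. A correlated attribute mixes the standardized
driver with an independent field carrying the attribute's own
variogram, $z = \rho z_{drv} + \sqrt{1-\rho^2}\, z_{ind}$, so the
marginal structure is preserved while the pointwise correlation matches
in expectation. Log-flagged attributes are simulated log-gaussian with
the arithmetic mean moment-matched to the target. The 10-measurement-
day temporal dimension of the original campaign is collapsed to
per-point aggregates: the downstream analysis is purely spatial.

`simulate_microbiology()` draws the nine two-region variables
(marker genes, enzymes, MBC, C/N) with SD = SE·√n per group, normal or
moment-matched log-normal per variable (copy numbers are log-normal).
The packaged group means are the reported values; the SEs — and the
cellulase means — are *synthetic plausible values* on each assay's
scale, because the originals exist only graphically. They were chosen
once from power arithmetic (noncentrality vs. the t critical value at
df = 16) so that the documented significance pattern is the generator's
expected behavior, not a tuned outcome; the file name marks them
synthetic.

What the generator does **not** emulate: rainfall-driven temporal
dynamics, anisotropy, non-Gaussian marginals beyond the log-normal
cases, cross-correlation structure among more than one driver, and the
composite (15-subsample) field sampling of the microbiology points.
Passing tests therefore demonstrate correctness of the estimators under
the stated stochastic model, not fidelity to every feature of real
field data.

## Problem sizes and runtime

The test and acceptance workloads are sized for interactive use: 100
random configurations of ≤ 30 points for the estimator-vs-enumeration
check, 50 replicate fields on the 100-point grid for parameter
recovery (median fitted nugget/sill within 25% of truth, range within
40%), 200 replicates for the two-region significance pattern at
α = 0.01, and 1000 replicates for the type-I calibration. The whole
suite runs in well under a minute.

## Known limitations

* Isotropy is assumed throughout; no anisotropic or space–time
  variography.
* Only ordinary kriging: no universal, co-kriging or conditional
  simulation.
* The log-scale maps are not back-transformed (the naive exponential
  back-transform is biased; a proper lognormal-kriging correction is
  out of scope).
* The SDI model factors and thresholds are validated only against the
  24 packaged survey rows; treat them as configuration when applying
  the index outside that context.
* Coordinates are planar meters with an arbitrary origin — no CRS or
  geographic projection handling.
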