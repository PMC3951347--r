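---
title: "Methods: spatial inference for class-structured predation kill sites"
author: "killzones package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial inference for class-structured predation kill sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Where a predator kills its prey is not random: habitat structure shapes
encounter rates, hunting success and the prey's own risk-sensitive habitat
decisions, and prey of different life-history classes (e.g. prime-aged
versus senescent animals) may die in systematically different places. Given
carcass locations labelled by prey class on a bounded landscape (an island
is the clean case: a closed system with a well-defined observation window),
this package answers three questions per class:

1. Are kill sites spatially clustered beyond complete spatial randomness
   (CSR), and out to what distance?
2. Where are the *kill zones* — the core of the kill-site density surface —
   and how fragmented are they?
3. Which habitat features are associated with a high probability of kill
   occurrence, once the spatial correlation of nearby sites is accounted
   for?

Because no field data ship with the package, a synthetic-landscape module
generates islands, habitat rasters and kill-site point processes with known
ground truth; every statistical component is validated by recovering that
truth.

## Clustering: Ripley's K/L with Monte-Carlo envelopes

For a pattern of n points in a window of area A,

K(t) = A / (n(n-1)) * sum over ordered pairs (i, j) of w_ij 1[d_ij <= t],

estimated in circular distance bands of 1 km by default. The linearized
form L(t) = sqrt(K(t)/pi) - t is zero under CSR, positive under clustering
and negative under dispersion. Edge effects in an irregular island window
are removed by Ripley's isotropic correction: w_ij is the reciprocal of the
proportion of the circle centred on point i with radius d_ij that lies
inside the window. That proportion is evaluated numerically over 64 equally
spaced angles (lakes count as outside); 64 angles resolve the proportion to
~1.6%, far below the Monte-Carlo noise of the envelopes, and the weight is
capped at the number of angles. The per-angle inside test runs either
against the exact polygon or - the default, and the path the envelopes use -
against a precomputed 60 m raster mask of the region, which is orders of
magnitude faster at an additional error of order cell size / circle
circumference (well under the angular resolution); circles closer to the
window edge than their radius skip the test entirely, since their weight is
exactly 1. The
uncorrected estimator is retained both for oracle tests (it must equal a
brute-force pair count exactly) and because simulation shows its bias at a
quarter of the window width, which the correction removes.

Significance uses pointwise rank envelopes: 99 CSR simulations of the same
n in the same window, with the envelope taken as the per-band minimum and
maximum, giving a one-sided pointwise test at alpha = 1/(99+1) = 0.01.
Envelopes at other alpha use the matching order statistics. Rank envelopes
at a single band are exactly calibrated by exchangeability, which the test
suite verifies empirically (500 independent CSR patterns against fresh
99-simulation envelopes). Global (simultaneous) envelopes are deliberately
out of scope.

## Kill-occurrence surfaces: KDE with LSCV bandwidths

The kill-site density is an isotropic Gaussian kernel estimate with a
single scalar bandwidth per class, evaluated on a raster (100 m cells by
default), truncated to the island and renormalized to unit mass. The
bandwidth minimizes the least-squares cross-validation criterion

LSCV(h) = integral of f-hat^2 - (2/n) sum_i f-hat_(-i)(x_i),

with the integral term in closed form (a Gaussian kernel convolved with
itself is a Gaussian kernel at bandwidth h*sqrt(2)). The criterion is
evaluated on a log-spaced grid and refined by golden-section search. Two
numerical guards matter in practice:

* the default search grid runs from the mean nearest-neighbour distance up
  to a quarter of the point-cloud extent. LSCV's well-known failure mode is
  chasing individual points toward h -> 0; below the nearest-neighbour
  scale there is no density structure that a cross-validated estimate can
  legitimately resolve, so the grid excludes it.
* exact repeat locations make LSCV degenerate, so coincident points are
  jittered by 10 m (0.1 of the default surface cell) with a warning before
  selection.

The *percentile transform* converts density height into the probability
scale the regression uses: percentile(cell) = 100 x (probability mass in
cells with density <= that cell's density), so the densest cell scores 100.
The "top p%" region is the highest-density cell set holding p% of the
probability mass (the home-range convention of probability-mass isopleths,
not area percentiles — the two differ whenever density is non-uniform, and
the mass convention is the one under which "the height of the KDE is the
probability of kill occurrence" is coherent). Ties in density share a
percentile; region extraction uses a deterministically tie-broken inclusion
rank so that "top p%" is well defined even on flat surfaces.

## Core (kill-zone) delineation by Monte-Carlo CSR comparison

The core search asks: at which mass percentile p does the observed pattern
concentrate most strongly relative to chance? For each candidate p in
1..99 the observed enrichment is e(p) = f(p) - a(p), with f(p) the fraction
of kill sites inside the top-p% region of their own KDE and a(p) that
region's share of the island area. The null distribution of e(p) comes from
CSR replicates pushed through the *identical recipe*: each replicate draws
n CSR points, selects its own LSCV bandwidth, builds its own surface on the
same grid, and scores its own points. This design is what makes the test
both calibrated and powerful:

* scoring CSR points on the *observed* surface would be biased — the
  observed points built that surface, so their f(p) exceeds a(p) by
  construction even under CSR;
* scoring replicates on their own surfaces but with the observed bandwidth
  destroys power — with a small (clustered-data) bandwidth every pattern,
  CSR included, concentrates in its own kernels.

Re-running bandwidth selection per replicate restores exchangeability under
CSR (verified: the no-core sentinel is returned in >= 90% of CSR runs)
while a clustered pattern earns a small bandwidth and compact high-density
region that CSR replicates cannot imitate. Because 99 dependent candidates scanned at 5% each would
find spurious cores under CSR well above the nominal rate, departure from
CSR is first established by a family-wise gate: the maximum enrichment over
all candidates against its own Monte-Carlo null (an exact test by
exchangeability). When the gate rejects, the returned core percentile is
the smallest p whose enrichment is maximal among candidates with pointwise
exceedance probability < 0.05 (10000 iterations by default); otherwise a
no-core sentinel (NA) is returned. The
cited Bayesian core-area framework this operationalizes is only sketched in
the literature the analysis follows; the rule above is this package's own
concrete construction and is reported as such in all outputs.

For *cross-class comparison* the pipeline extracts each class's kill zone
at a common reference isopleth (top 30% by default) — comparing zones of
equal probability mass is the only way polygon counts and areas are
commensurable between classes — while the core-search percentile and its
significance are reported alongside. Zone polygons come from 8-connected
component labelling of the selected cells followed by edge-cancellation
ring tracing (outer rings counter-clockwise, holes clockwise; at a
corner where components touch diagonally the tracer takes the sharpest
left turn, keeping each ring simple).

## Habitat covariates and standardization

Six covariates are averaged in a 100 m diameter (0.79 ha) buffer around
each kill site — elevation (m), slope (degrees), canopy proportion,
conifer proportion, distance to shore (m), distance to the nearest inland
lake (m) — using the cells whose centers fall within the radius
(center-in-circle rule; buffers clipped by the coast use inside cells
only, and a site whose buffer holds no cell center falls back to the
nearest masked-in cell). Covariates are z-scored with the sample (n-1)
standard deviation on the *pooled* two-class site set: per-class scaling
would make standardized coefficients incomparable between the class
models, which is the comparison the analysis exists to make.

## Spatial regression

Per class, the KDE percentile at each kill site (0-100, treated as
Gaussian) is regressed on the standardized covariates with spatially
autocorrelated errors:

y = X beta + e,  Cov(e) = tau^2 I + sigma^2 k(d / phi),

with k exponential by default (gaussian and spherical are options; the
covariance family is this package's choice — the analysis tradition cites
only "a spatially autocorrelated covariance structure"). Estimation is
REML: the nugget proportion and range are optimized numerically
(Nelder-Mead on transformed parameters, three log-spaced range starts,
convergence tolerance 1e-10 on the criterion), with the overall scale and
beta profiled analytically through a Cholesky factorization. The
pure-nugget boundary (sigma^2 = 0, i.e. ordinary least squares) is
evaluated exactly as a candidate, so independent-error data reduces to the
OLS closed form rather than merely approaching it. Standard errors come
from the profiled information; a 1e-8 relative ridge guards the
decorrelation step when the fitted nugget is near zero and sites nearly
coincide.

Diagnostics whiten the residuals with the fitted covariance factor, then
apply the Shapiro-Wilk statistic (normality) and a score test of squared
whitened residuals on whitened fitted values (homoscedasticity; LM = n R^2
against chi-square, 1 df). The reduced model refits after removing every
non-intercept coefficient whose interval beta +/- se contains zero — the
literal "standard error overlaps zero" rule, with a z-based (1.96 se)
variant available — and records what was removed. Standardized
coefficients translate to natural units as beta * delta / sd(column),
e.g. percentiles per 10 m of elevation.

The enrichment of kills inside the pooled kill zones is a one-degree
goodness-of-fit chi-square of the inside/outside split against the zones'
area share of the island; because per-class zones may overlap, the pooled
area fraction is the class-size-weighted mean of per-class fractions, and
per-class tests are reported alongside.

## The synthetic landscape: what it emulates and what it does not

`generate_island` builds an elongated (aspect >= 3) island of 544 km^2 by
default as a smoothed random radial perturbation of an ellipse — the
construction is star-shaped, hence the ring is guaranteed simple — with
1-3 circular inner lakes and the land area rescaled to the target exactly.
Habitat fields are Gaussian random fields synthesized by circulant
embedding with exponential correlation, parameterized by the *practical*
range (the distance at which the variogram reaches ~95% of its sill):
elevation (mean 240 m, sd 55 m, range 9 km) is transformed linearly,
canopy (0.60, range 7.5 km) and conifer (0.35, range 6 km) proportions
logistically; an optional fine-scale variance fraction can be mixed into
any field to mimic stand-level patchiness. Slope is the finite-difference
gradient of elevation, and the two distance layers are exact distances to
the coastline and lake outlines. Negative embedding
eigenvalues are clamped and the field rescaled to unit variance; sample
moments and the empirical variogram are checked in the test suite.

Kill sites follow a log-linear intensity over the standardized covariates,
sampled by thinning with a 1.001 safety factor on the maximum cell
intensity, optionally with fixed-n Thomas-style clustering: parents drawn
from the same intensity, each point a Gaussian displacement of a uniformly
assigned parent, re-drawn until inside the region, and thinned by the
habitat intensity relative to its maximum within the parent's 3-sigma
neighbourhood (a local envelope, so within-cluster placement tracks the
covariates without collapsing onto the globally best cells; an exponent
can temper it). The default two classes encode the study conditions the
package emulates: class_a ("prime-like", n = 106) in ~18 small near-shore
clusters (sigma = 600 m) with canopy +1.2, conifer -2.0, shore-distance
-1.0; class_b ("senescent-like", n = 109) in a single wide inland zone
(sigma = 3000 m, habitat-placed parent) with elevation +2.0, conifer +1.5,
shore-distance +0.5. Effect sizes are deliberately strong: the end-to-end
tests are sign-recovery tests, and weak planted effects would conflate
estimator noise with pipeline defects.

What the generator does *not* emulate: real coastline geometry, correlated
covariates (fields are independent; real canopy and conifer covary),
classification error in the class labels, observation effort gradients
(every kill is found), and temporal structure (years are pooled). Passing
tests therefore demonstrate that the inference chain recovers known
structure from data of this idealized kind, not that any particular field
system satisfies the model.

## Numerical choices and problem sizes

* Edge correction: 64 angles per pair against a 60 m region mask (exact
  polygon tests available); weights capped at 64.
* Distance ties at band edges: closed comparison (d <= t).
* KDE kernel truncated at 6 bandwidths (relative error < 1e-7).
* Surface grid warning when cells exceed h/2.
* Core search: candidates 1..99; Monte-Carlo p-values use the add-one
  (k+1)/(n+1) convention; significance level 0.05 per candidate.
* GLS optimization floors the nugget proportion at 1e-6 during search.
* The analysis scripts and the acceptance script run the full 544 km^2
  island at 120 m habitat cells and 250 m KDE cells; the package defaults
  (30 m / 100 m) match the emulated data products and remain available.
  The test suite uses 60 km^2 islands and coarser grids, with Monte-Carlo
  iteration counts of 150-500 where the method default is 10000; all sizes
  are stated in the tests themselves.

## Known limitations

* The percentile response is bounded (0-100) but modelled as Gaussian, as
  in the analysis tradition this follows; no logit transform is applied.
* Pointwise (not global) envelopes: interpreting the clustered-distance
  range reads the envelope at many bands jointly.
* The core-search rule is an operationalization of a sketched method, not
  a reproduction of its internals; results are labelled accordingly.
* LSCV bandwidths remain variable at n ~ 100 even with the bounded search
  grid; kill-zone polygon counts at a fixed isopleth inherit that
  variability.
* The enrichment chi-square treats the zone as fixed when counting points
  inside it, as the summary statistic tradition does; it is reported as a
  description of concentration, not an independent test of clustering.
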