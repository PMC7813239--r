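---
title: "Methods: maximum-entropy habitat suitability with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy habitat suitability with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Screening candidate translocation sites for a threatened species requires
a habitat-suitability model built from presence-only records: occurrence
archives record where a species was seen, never where it is absent. The
maximum-entropy (Maxent) framework handles this by contrasting presences
against *background* points sampled from the candidate extent, estimating
the distribution over environments that is closest to uniform while
matching the feature means observed at presences. maxentSDM implements
that framework end to end for raster predictors, with a particular focus
on rock-dwelling species whose suitability is governed by terrain
roughness, and validates it on synthetic landscapes where the true
suitability surface is known.

# Model

## Features

Only hinge features are used. For a predictor $x$ with fitted range
$[x_{\min}, x_{\max}]$ and knot $t$, the forward hinge is
$\max(0, x - t) / (x_{\max} - t)$ and the reverse hinge
$\max(0, t - x) / (t - x_{\min})$, both in $[0, 1]$ and clamped there when
a prediction point falls outside the fitted range. Hinge-only models give
additive piecewise-linear responses on the link scale — flexible enough
for saturating and unimodal shapes, smooth enough to transfer. Knots are
placed at `knotsPerVariable` (default 30) evenly spaced quantiles of the
pooled presence + background values; tied quantiles are collapsed and
knots at the range limits dropped, so low-cardinality or constant
predictors contribute few or no features. The knot count is a package
default (the reference literature does not prescribe one) and is recorded
in the run manifest.

## Objective and solver

With $m$ presences, $N$ background points, and feature matrix rows
$f(x) \in [0,1]^J$, the coefficients minimize

$$-\frac1m \sum_{i \in \text{pres}} \eta(x_i)
  + \log \sum_{x \in \text{bg}} e^{\eta(x)} - \log N
  + \sum_j r_j \lvert \lambda_j \rvert, \qquad
  \eta = \textstyle\sum_j \lambda_j f_j,$$

with per-feature penalty $r_j = \beta \sqrt{s^2_j / m}$, where $s^2_j$ is
the feature variance over presences — the standard hinge regularization
rule — and $\beta$ the global multiplier (default 2.5, a deliberately
strong setting that favours smooth responses suited to extrapolating
beyond the occupied range). The objective is convex; the solver is cyclic
coordinate descent with soft-thresholding, in compiled code, with these
numerical choices:

* each coordinate takes a proximal Newton step using the current Gibbs
  variance of its feature as curvature, then backtracks (step halving)
  whenever the step would increase the full objective — the log-partition
  term is not quadratic, so unguarded Newton steps can overshoot;
* presence variances are floored at $10^{-6}$ when forming $r_j$ so that
  features constant across presences keep a nonzero penalty;
* coefficients are confined to $[-\lambda_{\max}, \lambda_{\max}]$
  (default 30). With completely separable presences the penalized
  objective can decrease without bound along a coefficient direction;
  the box keeps the optimum finite and does not affect interior
  solutions, which is where all scientifically meaningful fits live;
* convergence is declared when the objective changes by less than
  `convergenceTol` (default $10^{-7}$) relative to $|\text{objective}| +
  1$ over a full sweep; non-convergence within `maxIterations` is an
  error carrying the last objective value, never a silent result.

The tests verify the solver against an independent, iteratively refined
dense grid search over the same objective on one- and two-feature
problems.

## Output scales

The raw output $q(x) = e^{\eta(x)}/Z$ normalizes to one over the training
background. The logistic output is
$p = \tau e^H q / (1 - \tau + \tau e^H q)$ with $H$ the entropy of $q$
over the training background and $\tau$ the assumed prevalence (default
0.3, reflecting a species that is hard to detect). A site whose
environment is "average" under the model ($e^H q = 1$) scores exactly
$\tau$. Prevalence affects only this output transform, never the fitted
coefficients; the package makes that choice explicit because the
reference literature leaves it ambiguous.

## Evaluation, ensembling, interpretation

Models are evaluated by repeated k-fold cross-validation (defaults k = 10,
10 repeats): presences and background are partitioned independently per
repeat, features are rebuilt from each training fold, and held-out AUC
(rank-based Mann–Whitney, ties counted half) and TSS (sensitivity +
specificity − 1, maximized over all unique score thresholds, smallest
threshold on ties) are computed on the held-out points. The ensemble keeps
the best fold-model of each repeat by held-out AUC — our reading of
"all the best models derived from each k-fold sampling" — and weights
members by $(\mathrm{AUC} - 0.5)_+$, normalized. Raw-AUC weights barely
differ between competent members; skill above chance is the documented,
testable alternative. If no member beats chance the weights fall back to
uniform with a warning.

Interpretation tools:

* *response curves*: one predictor swept over its fitted range, all others
  held at their presence means;
* *permutation importance*: mean held-out AUC drop over seeded
  permutations of one predictor across the evaluation points, clamped at
  zero and normalized to sum one; predictors with no active feature score
  exactly zero;
* *limiting factors*: per cell, the predictor whose replacement by its
  presence mean most increases the logistic prediction; exact ties (and
  cells where no replacement helps) resolve to the first variable in the
  canonical layer order (roughness, aspect_north, woodland, grassland,
  tmin_july, precip_ann).

## Hold-out null-group validation

A geographically disjunct group of hold-out sites is scored against the
distribution of the same statistic (mean and median) over B groups of g
distinct cells (defaults B = 10000, g = 9) drawn uniformly from the masked
extent. Groups are sampled without replacement within a group — a "group
of distinct sites" — and independently across groups. The p-value is the
add-one permutation form $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(B + 1)$, which cannot be zero under finite resampling. Both the
normal-approximation CI of the mean of group means and the empirical
2.5/97.5 percentiles are reported, because the two summaries answer
different questions and published reports often leave the choice implicit.

# Predictors

* **Terrain roughness**: max − min elevation over each cell's 3×3
  neighbourhood, computed on the fine grid and block-averaged to the
  coarse grid. Neighbourhoods truncated by edges or nodata use the cells
  present; fewer than two valid cells give nodata.
* **North-facing aspect fraction**: downslope aspect of each fine cell
  from central differences (one-sided at edges; Horn's method available
  via config), percentage of non-flat fine cells per coarse cell whose
  aspect lies in [315°, 45°). The window is configurable; a symmetric
  quadrant about north is the conventional default. Flat cells have no
  aspect and leave both numerator and denominator — counting them as
  "not north" would silently deflate percentages on plains.
* **Woodland and grassland fractions**: per coarse cell, the fraction of
  fine vegetation cells in the woodland (respectively grassland) code
  sets, with excluded codes (water, cleared land, unknown) omitted from
  the denominator entirely, following the convention that non-habitat
  classes are left out of cover calculations.
* **Climate**: minimum temperature of the coldest month and mean annual
  precipitation pass through unchanged on the coarse grid.

Collinearity is screened with a Spearman rank matrix over predictor values
at an explicit point set (presences + background); the point set is an
argument because correlation magnitudes depend on it. Short edge blocks
are aggregated over the cells present rather than dropped, so derived
grids never shrink the extent. All rasters must share one equal-area grid;
reprojection is out of scope.

# The synthetic landscape and virtual species

The generator emulates the structure of the real inputs this workflow
targets without reproducing any real geography:

* *elevation*: white noise smoothed by an isotropic Gaussian kernel (FFT
  circular convolution), rescaled to [0, 2400] m on a fine grid of
  4×4 subcells per coarse cell (emulating 250 m cells within ~1 km
  cells). The scale is chosen so block-averaged roughness spans well past
  the species' saturation point, as on real rocky ranges;
* *climate*: minimum temperature = base − lapse-rate × elevation +
  latitudinal gradient + autocorrelated noise; precipitation = base +
  orographic term + latitudinal gradient + noise. The orographic
  coefficient is kept small (0.15 mm/m) so that precipitation is not a
  proxy for elevation — with strong coupling, the model cannot attribute
  effects between roughness and rainfall, and neither could any model;
* *vegetation*: a smoothed field thresholded at quantiles into woodland,
  grassland, shrubland, water and cleared classes (35/25/20/8/12%),
  the last two excluded from cover denominators;
* *virtual species*: logistic in a saturating roughness ramp
  ($\min(r, r^*)/r^*$ with $r^* = 220$ m), bounded unimodal quadratics in
  precipitation (optimum 800 mm, zero at 500/1100 mm) and temperature
  (optimum 5 °C, half-width 5 °C), and woodland fraction. The quadratic
  terms are clamped at −1: past-tolerance conditions are simply
  unsuitable, not unboundedly so, and the clamp keeps each predictor's
  influence proportional to its coefficient. Coefficients (12, 2.5, 1.5,
  0.75, intercept −11) define a sparse, strongly roughness-driven
  species: most of the landscape is near-unsuitable while rugged cells
  with benign climate approach certainty. Occurrences are drawn with
  probability proportional to suitability, placed at cell centers
  (optional jitter), and contaminated with exact duplicates and
  coarse-uncertainty records for the filters to remove.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data — includes sampling bias along roads and
towns, spatial clustering of survey effort, positional error other than
the declared uncertainty field, temporal drift, and taxonomic confusion
beyond a simple flag column. The hold-out region is a plain rectangle,
not a biogeographic unit.

`generateLandscape()` returns the fine and coarse layers as two aligned
stacks (they cannot share one geometry); everything else consumes and
produces single-geometry stacks.

# Pipeline and reproducibility

`runPipeline()` executes simulate → prepare → evaluate → predict →
limiting → validate for each configured background design (defaults: a
"restricted" design of 10000 points inside the training-occurrence
bounding box grown by 10%, standing in for a natural-range extent, and a
"full" design of 30000 points over the whole landscape), writes every
intermediate as GeoTIFF/CSV/JSON, and records configs, per-stage seeds
and md5 digests of all outputs in a manifest. Stage seeds are a
deterministic 31-bit hash of the master seed and the stage name, so
adding or removing optional stages never shifts the randomness of later
ones. Stages communicate only through files; any stage can be rerun from
persisted inputs. A missing hold-out region skips validation with an
explicit manifest entry. Background points are sampled with replacement
across eligible cells, since requested counts can exceed the distinct
cells of a small extent; duplicate background points are therefore
possible and intentional.

GeoTIFF input/output is a minimal single-band implementation
(uncompressed 64-bit float samples, ModelPixelScale/ModelTiepoint
georeferencing, nodata declared in the GDAL_NODATA tag) so that values
round-trip bit-exactly and files open in standard GIS tools; multi-band
or compressed files are rejected with explicit messages. Model state
serializes to JSON at 17 significant digits, which round-trips doubles
exactly.

# Problem sizes used by the test-suite

The suite exercises the complete workflow at desk scale, chosen to keep
a full run in minutes on one core while leaving every statistical check
well-powered: the default 120×120-cell landscape (480×480 fine grid);
600 virtual occurrences and 3000 background points with 4-fold, 2-repeat
cross-validation for the twenty parameter-recovery replicates; 1000 null
groups and 500 replicates for the calibration study of the null-group
test; and 250–300 occurrences with reduced background counts for the
byte-identity pipeline runs. The acceptance script uses 1400 occurrences,
two background designs of 4000 and 8000 points, 5-fold × 3-repeat
cross-validation and 10000 null groups. The spec-level defaults (k = 10
folds, 10 repeats, 10000/30000 background points) remain the package
defaults for real analyses.

# Known limitations

* The solver recomputes background moments per coordinate; for feature
  counts far beyond a few hundred, a gradient-caching strategy would be
  faster.
* Cross-validation folds are random, not spatially blocked; with strongly
  autocorrelated data random folds flatter the held-out metrics.
* The null-group test draws unconstrained random cells; it does not match
  the internal spatial clustering of the hold-out group.
* Exact numerical replication of the original Java Maxent coefficients
  (with its interpolated regularization tables and feature-class
  heuristics) is a non-goal; the implementation follows the published
  objective instead.
* No reprojection: all inputs must arrive on one equal-area grid.
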