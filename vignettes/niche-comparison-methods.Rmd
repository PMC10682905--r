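---
title: "Comparing ecological niches along a domestication gradient: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ecological niches along a domestication gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichegrad)
```

## The problem

Crop domestication reshapes not only plants but the portion of geographic
and environmental space in which they occur. In a center of origin, wild
populations, tolerated semiwild plants, farmer landraces and modern
commercial cultivars coexist, and one can ask whether each step along that
gradient expanded, contracted or shifted the realized niche — and how
climate change will redistribute the suitable area of each class.

`nichegrad` implements the full comparative workflow as reusable, tested
code: occurrence preprocessing, PCA environmental envelopes, per-class
maximum-entropy suitability models, niche-overlap statistics with
randomization tests, and future-scenario change accounting. Because the
workflow's real inputs (curated occurrence deposits, global climate
surfaces) are large external downloads, the package ships a first-class
synthetic-data module whose ground truth is known, so every downstream
stage is verifiable end to end.

## The suitability model

The core model is presence–background maximum entropy. Over the background
cells $z$ of the study region the model is the Gibbs distribution

$$q_\lambda(z) = \frac{\exp(\lambda \cdot f(z))}{Z_\lambda},\qquad
Z_\lambda = \sum_z \exp(\lambda \cdot f(z)),$$

with features $f$ drawn from the LQHP vocabulary — linear, quadratic,
hinge (forward/reverse ramp pairs at background quantile knots) and
pairwise products — all min–max scaled to $[0,1]$ on the training
background. Fitting maximizes the L1-penalized mean presence log-likelihood

$$\ell(\lambda) = \tfrac1m\sum_{i \le m} \lambda\cdot f(x_i) - \log Z_\lambda
 - \sum_j \beta_j |\lambda_j|,$$

a concave objective solved by proximal gradient ascent with backtracking,
so the objective trace is non-decreasing by construction (and asserted in
tests). Penalties follow the conventional form
$\beta_j = r\,\beta_0(\text{class}_j, m)\, s_j/\sqrt m$ with $s_j$ the
background SD of feature $j$ and $r$ the user-facing regularization
multiplier. The base constants $\beta_0$ are documented constants of this
implementation: linear/quadratic/product interpolate
$(m{=}10, 1.0) \to (30, 0.2) \to (100, 0.05)$, hinge is $0.5$.

Projection uses the standard logistic output
$\;q e^H / (1 + q e^H)$, where $H$ is the entropy of the fitted
distribution over the training background; with all weights zero this is
exactly $0.5$ everywhere. Clamping (on by default) restricts
projection-time variable values to the training range and flags the cells
affected — the configuration used throughout the pipeline, since study
regions truncated at political borders create artificial sampling
barriers.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| thinning distance | 5 | km | removes duplicate sampling of one grid cell (~2.5 arc-min ≈ 5 km) |
| background size | 10 000 | cells | standard presence–background scale |
| test fraction | 0.3 | — | held-out presences per replicate |
| replicates | 10 | — | independent seeded 70/30 splits; median/SD maps aggregate them |
| max iterations | 500 | — | optimizer cap; convergence flag recorded |
| regularization multiplier | 3 (wild-side), 1 (commercial/cultivated) | — | stricter smoothing where sampling is organic; per-class map in the config |
| hinge knots | 30 | per variable/direction | flexibility vs. fit time at desk scale |
| study-area buffer | 3 | degrees | disk buffer around the all-points convex hull |
| threshold percentile | 10 | % of training presences | binary range maps; the present-derived threshold is reused for all futures of a class |

Replicated evaluation is implemented as ten independent seeded 70/30
splits (sometimes loosely called cross-validation in this model family);
independent splits are what the median/SD aggregation actually requires.

## Overlap statistics and randomization tests

Suitability surfaces are compared after normalizing each to sum 1 over the
shared valid cells: Schoener's $D = 1 - \frac12\sum|p-q|$, Warren's
Hellinger-based $I = 1 - \frac12\sum(\sqrt p - \sqrt q)^2$, plus Spearman
rank correlation on the raw values. $D$ and $I$ are symmetric, invariant
to positive rescaling, and equal 1 exactly when the normalized surfaces
coincide ($I \ge D$ is *not* a theorem and is not asserted).

The *equivalency test* pools the two classes' presences, shuffles labels
preserving sample sizes, refits both models and recomputes $D$/$I$ per
repetition; a small lower-tail p-value rejects equivalency. The
*background test* replaces one class's presences with random draws from
its available region and refits only that class; its two one-sided
p-values distinguish "more similar than random" (the signature of a niche
nested inside the other) from "less similar than random" (divergence). The
test is asymmetric by construction and is run in both directions to probe
nesting. Empirical p-values use the $(\text{count}+1)/(n+1)$ correction
and are never zero. Because these tests refit models hundreds of times,
their default configuration is deliberately reduced (linear+quadratic
features, 2 000 background cells, single fit); feature matrices for the
fixed background and projection cells are computed once and reused across
repetitions.

The environmental-space variant follows the standard occupancy-grid
method: a PCA of the background environment, Gaussian-kernel densities of
occurrences and background on a 100×100 grid over PC1–PC2, occupancy =
occurrence density / background density (zero where the background
vanishes), and $D$/$I$ on the normalized occupancy grids. Several variants
of this estimator circulate; the standard occupancy-grid formulation above
is the one implemented, and resolution insensitivity (|ΔD| < 0.05 between
50 and 200 grid cells) is tested.

## Envelopes, intervals, letters

Environmental envelopes are minimum convex hulls in the space of the first
two components of a correlation-matrix PCA (variables are z-scored because
units are heterogeneous — °C, mm, CV%). Overlap is reported **both** as
area fractions (intersection over each hull's area, and over the union)
and as point-density fractions (share of each class's points inside the
intersection polygon), because area alone is sensitive to point clustering
and uneven sampling; reports label each convention explicitly. Where a
single "both-classes" overlap percentage is wanted, intersection/union is
this package's convention, and reports say so.

Per-variable class comparisons use the percentile bootstrap (1 000
resamples, 2.5/97.5 percentiles; statistic defaults to the mean, median by
flag). Compact letter displays are derived
from the interval-overlap graph: letters are its maximal cliques (for
intervals, the sets of intervals covering a common point), so two classes
share a letter if and only if their intervals overlap.

## Futures accounting

Binary range maps threshold the replicate-median suitability map at the
$k$-th smallest training-presence score, $k = \lfloor p/100 \cdot n
\rfloor + 1$ — an exact order statistic on small $n$, deliberately without
interpolation. The same present-derived threshold is applied to every
future projection of that class. Change is reported as the conserved
decomposition lost/retained/gained ("shift", often quoted as a single
number without a standard definition, is deliberately reported as the
(lost, gained) pair), per GCM and for the stringent all-GCM intersection;
"area" is unmasked-pixel count — the unambiguous unit on a fixed grid —
with a cos(latitude)-weighted variant available. Model transferability is screened with MESS
(multivariate environmental similarity surfaces); a cell is negative
exactly when at least one variable leaves its training range, an
equivalence asserted against a brute-force check. For a constant training
variable the similarity is defined as $-100\,|p - c|$ away from the
constant (flagged with a warning).

## The synthetic world

`make_env_layers()` builds bioclim-like layers: a deterministic
north–south temperature gradient and east–west precipitation gradient plus
smoothed Gaussian random fields, empirically whitened and Cholesky-mixed so
cross-layer correlations match the requested target essentially exactly.
Defaults reuse the nine-variable bioclim subset (BIO 2/3/4/5/9/14/15/18/19)
with realistic means and spreads.

True niches are Gaussian (bell) suitability surfaces
$s(e) = \exp(-\frac12\sum_v ((e_v - \mu_v)/\sigma_v)^2)$ — smooth,
unimodal, and nestable by construction, which is all the downstream
machinery needs as a recovery target. The stated class design:

* **wild** — optimum at the landscape center, tolerance ≈ half the
  landscape SD per variable;
* **landrace** — same optimum, half the wild breadth (strictly nested);
* **semiwild** — slightly shifted, 0.7× wild breadth;
* **commercial** — shifted toward dry, high-seasonality space, 0.8× wild
  breadth.

The wild tolerance was deliberately set well below the landscape spread:
the study region must contain environments unsuitable for the wild class,
otherwise background tests have no power for anyone (a near-uniform wild
surface is as similar to a random model as to the landrace model). This
ratio was fixed once as part of the stated world. Occurrences are sampled
with probability proportional to true suitability and jittered uniformly
within their cell; cultivated proxy points are drawn by rejection sampling
inside polygons, emulating coordinate proxies from agricultural land-use
polygons. Futures are warmed/precipitation-scaled copies of the present
layers: each pseudo-GCM carries a fixed climate-sensitivity factor
(0.75–1.25) and precipitation-response factor, applied to a mid-range
warming table (SSP2-4.5: +1.4/+1.9/+2.2 °C; SSP5-8.5: +1.9/+3.0/+4.4 °C
for 2050/2070/2090) plus smooth noise.

What the generator does **not** emulate: spatial sampling bias, species
interactions, non-Gaussian or multimodal niches, irrigation as a separate
driver, topography, and real climate covariance structure. A green test
therefore establishes that the machinery recovers known structure from
data that satisfy the model's assumptions — not that any particular real
dataset does.

## Numerical choices and degenerate inputs

* Cell location is its center everywhere; grids are top-left origin,
  row-major, y decreasing with row; cell assignment is half-open
  (x ∈ [left, right), cells span y ∈ [bottom, top)) so extraction is
  bit-reproducible on boundaries.
* Geometry equality tolerance is 1e-9 degrees; mismatched stacks are a
  hard error (no resampling in scope).
* Haversine distances use a fixed 6371-km Earth radius; ellipsoidal error
  is negligible at the 5-km thinning scale.
* Thinning is greedy in input order (deterministic; a seeded shuffle is
  available for sensitivity checks). Thinning is applied per class by
  default; the joint-then-split alternative is a documented switch left to
  the caller.
* PCA signs are fixed by making each loading's largest-magnitude entry
  positive; constant variables are hard errors in PCA and warnings
  (excluded) in the correlation filter.
* The optimizer stops at `max_iter` or an objective improvement below
  `tol` (1e-6); a convergence flag is always recorded.
* A single master seed fans out to per-stage child seeds by fixed offsets,
  recorded in the run manifest; reruns are byte-identical.

## Known limitations

No reprojection or resampling; single-band uncompressed GeoTIFF only (the
ASCII grid dialect is the canonical exchange format); no threshold or
categorical features; no sampling-bias surfaces; no dispersal constraints
or biotic layers in the future projections. The greedy correlation filter
and greedy thinning are order-dependent heuristics — deterministic and
documented, but not global optima.
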