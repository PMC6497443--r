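---
title: "Models and methods behind antnest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind antnest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate.

# The experimental setting

A colony of roughly 80 individually labelled carpenter-ant workers (plus the
queen) lives in a wooden nest chamber of 65 × 40 mm with a 6 mm entrance, and
is tracked at 1 Hz for four hours; the nest is then quadrupled to four
chambers chained by 6 mm openings and the colony is tracked again. Two data
tables result per recording: per-second positions (`ant_id, t, x, y,
presence`) and trophallaxis events (`ant_i, ant_j, start, end`, each at least
2 s long). A four-hour recording with both endpoints kept has 14,401
per-second rows per ant.

# Nest geometry and wall-aware distances

Chambers are closed axis-aligned rectangles; each opening is modelled as a
short corridor rectangle (6 mm wide, 2 mm long by default) so the walkable
region is a connected union of rectangles. The coordinate frame puts the
origin at the entrance midpoint with x increasing into the nest.

Ants cannot walk through walls, so two distances are wall-aware:

* **Geodesic distance** (`geodesic_distance()`): shortest in-region path.
  Within one rectangle this is the straight line (rectangles are convex);
  across rectangles it is computed by Dijkstra on an occupancy grid with
  8-connected moves (diagonals cost √2 × resolution and may not cut wall
  corners). The default resolution is 0.5 mm; the error of the grid metric
  is bounded by about one grid step plus the ~8% anisotropy inherent to
  8-connected lattices, which is well inside the 15–20 mm radii it is used
  with. Distance fields are cached per source cell, and callers that only
  compare against a radius pass a `cutoff` so that pairs whose Euclidean
  lower bound already exceeds it skip the grid entirely.
* **Rectilinear entrance distance** (`distance_to_entrance()`): shortest
  in-region path whose segments are parallel or perpendicular to the walls —
  the natural "how far to the exit" metric for an ant following walls. For
  points in a rectangle that touches the entrance point this is exactly the
  L1 distance (rectangles are L1-convex); elsewhere it is a 4-connected grid
  distance, floored at the unconstrained L1 distance.

The entrance reference point is the midpoint of the entrance opening on the
chamber wall. The nest-side end was chosen over the outer end of the entrance
tunnel because all in-nest paths terminate there; the choice shifts every
signature by at most the 2 mm tunnel length and is configurable
(`entrance_point`).

Camera alignment is a least-squares affine fit from the clicked chamber-corner
pixels to the known chamber dimensions (`fit_affine()`), requiring at least
three non-collinear correspondences; per-corner residuals are reported.
Points that land outside the nest after transformation (or interpolation) are
projected to the nearest point of the walkable region, which for a union of
rectangles is the nearest rectangle clamp.

# Spatial groups

An ant's **spatial signature** is the multiset of its entrance distances over
all in-nest seconds. Raw per-second samples are used, not thinned ones: the
similarity statistic below compares whole occupancy distributions, and
temporal autocorrelation affects both members of every pair symmetrically.

Similarity is `S(i,j) = 1 − KS(i,j)`, the complement of the two-sample
Kolmogorov–Smirnov statistic (the largest gap between the two empirical
CDFs). It is invariant to any common monotone rescaling of the distances.
The package evaluates the ECDFs of all ants on the pooled support, which
gives the exact pairwise sup-gaps in one pass.

Groups are found by Louvain modularity maximization on the weighted complete
similarity network (`igraph::cluster_louvain`). Louvain's greedy sweep
depends on vertex order, so the order is shuffled by the caller's seed and
the achieved modularity is attached to the result for near-tie diagnosis.
Groups are relabelled 1..k by increasing mean entrance distance; ants that
never entered the nest have empty signatures, are excluded from the network,
and are appended as group 0.

**Robustness** is scored by resampling every edge weight from a beta
distribution with mean equal to the observed similarity and second shape
parameter β = 4 (zero similarities get mean 0.001), i.e. `Beta(α, 4)` with
`α = 4μ/(1−μ)`. The stated shape parameter is read as the *second* shape
argument because, with the mean constrained, that reading yields a mean
relative perturbation of roughly 10% for mid-range similarities, matching the
intended severity; both the shape and the zero-edge mean are arguments. After
re-detection, an ant has "changed group" if fewer than half of the ants she
was grouped with in the smaller of her two groups (reference vs replicate,
ties resolved toward the reference) are present in the larger; the mean
changed fraction over 1000 replicates is reported.

**Consistency across treatments** is the Spearman rank correlation of the
ordered group labels of ants present in both recordings (case-wise deletion
of ants that died happens upstream), with a two-sided permutation p-value
(40,000 permutations by default).

# Local density

Local density of ant *i* at time *t* is the number of other in-nest ants
within 15 mm along wall-aware paths. Because the counts are strongly
correlated across ants and time, inference uses the colony mean per second
subsampled every 25 min (1500 s), giving 10 points per four-hour recording;
a lag-1 autocorrelation permutation test documents that the retained points
are effectively independent (a constant series is reported as a pass, since
no autocorrelation is estimable). The treatment effect is a linear mixed
model — fixed nest set-up effect, random colony intercept — tested by Wald
chi-square. This stage is deliberately a thin wrapper over `lme4`.

The random-diffusion null: if the colony spread uniformly over a nest
enlarged by a factor *a*, local density would fall by `100 (1 − 1/a)` % —
75% for the fourfold expansion. The Monte-Carlo cross-check in the tests
places 80 uniform points in 1× and 4× arenas and compares mean neighbour
counts away from the edges.

# Interaction rates and network assortativity

Per-second initiation counts (length 14,401 per recording; 86,406 rows for
three colonies × two treatments) are modelled by a Poisson log-link GLM with
colony, treatment, and their interaction under sum-to-zero coding, so the
intercept is the grand mean and reported levels are interpretable as
deviations. Pairwise contrasts of the per-colony (high − low) effects are
Wald tests on linear combinations of the coefficients; no multiplicity
correction is applied by default.

The trophallaxis network weights each dyad by its event count. Assortativity
with respect to the spatial partition is computed on the weighted mixing
matrix, `r = (Σ e_ii − Σ a_i b_i)/(1 − Σ a_i b_i)`, so each event contributes
once. The standard error is the edge jackknife: each unit of edge weight is
removed in turn and `se = sqrt(Σ (r_i − r)²)`. Event-weighted edges are the
default because interactions are counted, not dyads; a binarized variant is a
one-line `mutate` on the event table.

# The IHPP regression of trophallaxis initiation

For each unordered pair and second, the pair is *at risk* when both ants are
in the nest within 20 mm of each other (wall-aware by default; Euclidean by
flag, and automatically in single-chamber nests where the two coincide). The
rate is structurally zero otherwise, so non-at-risk seconds carry no
likelihood. With one-second discretization and λ constant within a second,
the likelihood `Π λ_t^{y_t} exp(−λ_t)` is exactly a Poisson regression with
log link on the at-risk pair-seconds; the printed exponent is taken with the
negative sign the Poisson process requires.

Covariates are the annular neighbour counts around the pair centroid: an
additional ant at distance d increments exactly one of n5 (d ≤ 5 mm), n10
(5 < d ≤ 10), n15 (10 < d ≤ 15), n20 (15 < d ≤ 20), so the four counts sum to
the total number of additional ants within 20 mm. The centroid is the
midpoint of the two positions, projected into the nest if a wall intervenes.
Colony enters as per-colony intercepts, treatment as a main effect,
colony × density interactions are always fitted, and the colony × treatment
interaction is fitted and dropped from the report when no term reaches the
5% level (`colony_treatment = "auto"`). Pairs are treated as independent;
seconds during an ongoing event of the pair stay at risk with y = 0 by
default, with censoring available via `censor_ongoing` (the natural choice
when events produced by the exclusive-engagement generator are analysed, see
below). Effects are reported as `100 (exp(b) − 1)` percent change in rate per
additional ant at each lag.

# The movement SDE

Velocity follows a continuous-time correlated random walk with spatially
varying drift and noise:

    dv = −β (v − μ(x)) dt + c(x) dW,     μ(x) = −c(x) ∇P(x)

β (1/s) sets directional persistence, the motility surface c(x) scales
movement noise, and the potential surface P(x) produces drift: the force is
proportional to the negative gradient, so ants move downhill on P. The sign
convention is fixed so that exported potential surfaces read "lower = faster
approach"; P is identified only up to an additive constant and is anchored to
mean zero, while c is reported on the `h³c²` residual-variance scale the
discretization defines.

The second-order discretization (step h = 1 s),

    x_t = x_{t−1}(2 − βh) + x_{t−2}(βh − 1) + βh² μ(x_{t−2}) + N(0, h³ c²(x_{t−2})),

is used both for simulation (`simulate_sde()`, with every step projected into
the nest) and for estimation: rearranged, the second difference of position
regresses on the backward velocity (coefficient −βh²) and on a
piecewise-constant drift field evaluated two steps back. The 1-D exposition
applies per axis with a shared scalar β and shared surfaces.

Estimation is three steps: (1) penalized least squares for β and the drift
field assuming uniform motility; (2) the motility surface from the step-1
squared residuals (`E[r²] = h³c²`), clamped at a small positive floor;
(3) a re-fit of β and the drift field weighted by `1/(h³ĉ²)`. Surfaces use
piecewise-constant basis cells on a 5 mm grid by default ("fine" relative to
the 65 mm chamber; 104 cells per chamber) with a squared discrete-Laplacian
penalty; the penalty weight is chosen by generalized cross-validation over a
log-spaced grid unless supplied. The potential is recovered from the drift
field by least-squares integration of `∇P = −μ/c` over the cell adjacency
graph. Records straddling outside spells are dropped; records at projection
(wall-contact) seconds are kept with their projected positions, which leaves
a small inward bias confined to boundary cells.

# The synthetic-colony generator

`colony_scenario()` defaults encode the study conditions: 80 ants, four-hour
recordings at 1 Hz, the one- and four-chamber nest layouts with 65 × 40 mm
chambers and 6 mm openings, two planted spatial groups (40/60 split, anchored
at the entrance- and queen-chamber centres, mirroring the observed ~39/60
occupancy split), and IHPP coefficients of the magnitude estimated for the
annular density effects (n5 = +0.18, n10 = +0.05, n15 = −0.41, n20 = −0.26 on
the log scale, intercept −5.8).

Movement uses the same discretized SDE the inference fits — per-group
quadratic potential wells (curvature 0.1 /mm) produce spatial fidelity; with
β = 0.5 /s and motility 1.0 the stationary spread around an anchor is ~4.5 mm,
so ants spend >95% of seconds in their home chamber while still mixing within
it. Trophallaxis initiations are drawn per at-risk pair-second with
probability `1 − exp(−λ_t)` from the same annular covariate coder the fit
uses; durations are `2 + Geometric(0.2)` s (only a lower bound of 2 s is
known, and a ~7 s mean is in the plausible range), and while a pair is
engaged neither partner initiates a new event. Generation/inference symmetry
is deliberate: recovery tests exercise the real covariate and likelihood code
paths, not a parallel implementation.

What the generator does *not* emulate: measurement noise in the clicked
positions, tag-reading errors, foraging trips (outside spells are optional
and all-or-nothing per ant), queen- or task-specific behaviour, and any
feedback from food exchange to movement. Passing recovery tests therefore
shows the estimators are correct for the stated model at realistic sizes, not
that the model captures every feature of real colonies.

# Problem sizes and tolerances used by the test suite

Chosen once as realistic desk-scale versions of the study design:

* Group robustness: 80 ants × 1800 s in the four-chamber nest, 1000
  perturbation replicates; detected groups must match the plant at ≥95% and
  fewer than 5% of ants may change group.
* IHPP recovery: 40 ants × 14,400 s in the one-chamber nest (~3.9 M at-risk
  pair-seconds, ~1000 events per draw); 20 replicates re-draw the point
  process on one movement realization — the IHPP likelihood conditions on
  the covariate paths, so event noise is the relevant sampling variation —
  with engaged pair-seconds censored to match the generator's exclusivity,
  and each annular coefficient must land within 2 SE of truth in ≥90% of
  replicates with the (+, +, −, −) sign pattern in every replicate. Note
  that a 2-SE interval covers ~95% of replicates, so requiring 18 of 20 per
  coefficient leaves a nontrivial chance of a one-replicate near-miss even
  for a perfectly calibrated estimator; such a miss, when the mean estimate
  across replicates is unbiased, should be read accordingly.
* SDE recovery: 20 tracks × 14,400 s; β within 10% and the motility median
  within 15% under flat truth; the fitted potential minimum within 2 grid
  cells of a planted well.
* Distance oracles: independent plain-R Dijkstra/BFS grid oracles on scaled
  small layouts (16–20 mm chambers) at 0.5 mm, 100 random pairs per layout,
  agreement within one grid step; Louvain checked against exhaustive
  modularity maximization on ≤8-node networks.

# Known limitations

* The grid geodesic inherits 8-connected anisotropy (≤ ~8% overestimate at
  worst-case angles); adequate for 15–20 mm radius queries, not for precise
  long-range path lengths.
* Louvain is greedy; on near-degenerate networks different seeds can return
  different near-optimal partitions (the attached modularity makes this
  visible).
* The mixed model treats the colony random intercept with only three
  colonies, so its variance is weakly identified — the Wald test of the
  treatment effect is the supported output.
* `fit_sde()` assumes a shared β across ants and treatments; per-recording
  fits are the way to compare conditions.
* Pair independence in the IHPP ignores that one ant's engagement suppresses
  its other pairs; with exclusive-engagement data the `censor_ongoing` flag
  aligns the likelihood with the generator, and at realistic event rates the
  uncensored default differs negligibly except for the intercept.
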