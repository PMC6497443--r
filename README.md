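# antnest

Analysis pipeline for per-second ant tracking and trophallaxis (mouth-to-mouth
food-sharing) data from nest-expansion experiments with carpenter ants.
Colonies of ~80 uniquely labelled workers are filmed for four hours at 1 Hz
inside a one-chamber (high-density) nest and again after the nest is
quadrupled to four chambers (low-density); the questions are how the colony's
spatial organization, local density, movement dynamics, and food-sharing
rates respond to the density change.

The package is written for behavioural ecologists working with tabular
tracking data: every user-facing function takes a tibble and returns one, so
stages chain with the pipe, and fitted objects have `tidy()` / `glance()` /
`autoplot()` methods.

## What it computes

* **Nest geometry** — chambers as axis-aligned rectangles joined by 6 mm
  openings; wall-aware (geodesic) distances and rectilinear
  distance-to-entrance on a configurable occupancy grid (default 0.5 mm);
  least-squares affine alignment of camera pixels to nest coordinates;
  projection of stray points back into the nest.
* **Preprocessing** — camera-clock alignment (including the one-second
  correction for every second GoPro Hero3 silver video), linear interpolation
  of tracking gaps with projection into the nest, yielding 14,401 per-second
  rows per ant per recording.
* **Spatial groups** — each ant's *spatial signature* is the distribution of
  its rectilinear wall-aware distance to the entrance over all in-nest
  seconds; pairwise similarity is `S = 1 − KS` (two-sample
  Kolmogorov–Smirnov statistic); Louvain community detection on the weighted
  similarity network yields spatial-fidelity groups, numbered by mean
  entrance distance with group 0 for ants that never entered. Robustness is
  scored by re-detecting groups on 1000 networks whose edges are resampled
  from beta distributions (shape 4) centred on the observed similarities,
  and cross-treatment consistency by a Spearman permutation test (40,000
  permutations).
* **Local density** — per-ant counts of other ants within 15 mm along
  wall-aware paths; colony means subsampled every 25 min (with a lag-1
  autocorrelation diagnostic) feed a linear mixed model (treatment fixed
  effect, colony random intercept, Wald chi-square test). The
  random-diffusion null predicts a `100 (1 − 1/ratio)` % density drop — 75%
  for a quadrupled nest.
* **Interaction rates and network** — Poisson log-link GLM of per-second
  initiation counts on colony × treatment under sum-to-zero coding
  (86,406 rows for the 3-colony design) with pairwise contrasts of the
  per-colony treatment effects; weighted trophallaxis network assortativity
  by spatial group with edge-jackknife standard errors.
* **IHPP regression** — trophallaxis initiations per pair modelled as a
  discretized inhomogeneous Poisson process: `log λ_t` is linear in colony,
  treatment, and the number of *additional* ants within 5/10/15/20 mm annuli
  of the pair centroid; λ_t ≡ 0 whenever the pair is more than 20 mm apart.
  Fitted by Poisson regression over at-risk pair-seconds; effects report as
  percent change in rate per additional nearby ant.
* **Movement SDE** — a continuous-time correlated random walk,
  `dv = −β (v − μ(x)) dt + c(x) dW`, with drift `μ(x) = −c(x) ∇P(x)` so ants
  drift downhill on a potential surface `P` while a motility surface `c`
  scales movement noise. Both surfaces are piecewise-constant on a grid with
  squared-Laplacian penalties; estimation is the three-step procedure (β and
  drift under uniform motility → motility from residuals → weighted re-fit).
  The same discretization simulates tracks, which is how the synthetic-data
  generator plants spatial groups (per-group potential wells).
* **Synthetic colonies** — `colony_scenario()` + `simulate_colony()` generate
  tracks and IHPP-driven trophallaxis events with known ground truth so every
  stage is testable end to end without the original video data.

## Worked example

```r
library(antnest)

scenario <- colony_scenario(n_ants = 80, duration_s = 1800)  # 4-chamber nest
sim <- simulate_tracks(scenario, seed = 1)
sig <- spatial_signatures(sim$tracks, scenario$nest)
net <- build_similarity_network(sig)
part <- detect_groups(net, seed = 2)
table(part$group)
#>  1  2
#> 32 48
attr(part, "modularity")
#> [1] 0.4249401

perturb_and_score(net, part, n_reps = 1000, seed = 3)
#> # A tibble: 1 × 3
#>   mean_changed_fraction max_changed_fraction n_reps
#>                   <dbl>                <dbl>  <int>
#> 1                     0                    0   1000
```

The colony splits into the two planted spatial groups (32 ants near the
entrance, 48 in the queen chamber; modularity 0.42), and none of the 80 ants
changes group in any of the 1000 beta-perturbed networks — the partition is
robust to substantial corruption of the similarity data.

`run_pipeline()` orchestrates the full set of stages from a config list (or
from track/event files on disk) and writes delimited outputs plus a
reproducibility manifest with the master seed and input digests.

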