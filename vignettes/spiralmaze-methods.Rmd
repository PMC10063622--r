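---
title: "Methods: double-spiral maze design and dispersal analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double-spiral maze design and dispersal analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralmaze)
```

## The problem

Minute walking insects (sub-millimetre egg parasitoids, mites and similar
organisms) disperse over metres and hours, but cannot carry tags and are
nearly invisible in the field. A double-spiral maze folds a metres-long,
centimetre-wide corridor into a plate that a single overhead camera can
image: individuals are released at the centre and photographed once per
minute against a bright back-light, each appearing as a dark blob a few
pixels long. Because the corridor is one-dimensional, every detection can be
summarized by a single signed coordinate `s`, its arc distance from the
introduction point, and group dispersal can be quantified by how the spatial
variance — the mean squared displacement (MSD) — grows over time.

`spiralmaze` implements the whole chain: arena design, synthetic
ground-truthed imagery, detection, mapping to the curvilinear coordinate,
detection cleaning, and the dispersal statistics.

## Maze geometry

The arena is a two-armed Archimedean spiral: arm A is `r(theta) = r0 +
b*theta`, arm B its point reflection through the centre, and the two arms are
joined by an S-curve of two semicircles. With `b = pitch/pi` the radial
spacing between successive corridor passes is exactly `pitch = path_width +
wall_width`, so corridor and wall widths are constant everywhere. Both arms
are congruent by construction: an individual turning left or right at the
release point experiences identical curvature at every distance.

Two design choices deserve comment:

* **Circular rather than stretched spiral.** Stretching the spiral to fill a
  non-square plate makes either the corridor width or the wall width vary
  around each turn. We keep the spiral circular — constant corridor width is
  a property worth more than the unused plate margins, and the default
  profile (440 x 330 mm plate, 10 mm corridor, 2.5 mm walls, 5.088
  turns/arm, frozen) still reaches 5.75 m of corridor.
* **S-curve radius.** The spiral arms start at `r0 = 2*pitch`, giving the
  central S-curve a radius of one pitch. With a smaller start radius the
  corridor folds onto itself at the centre, leaving a sub-raster wall
  pillar; the skeleton then shortcuts the S-curve and every arc coordinate
  inherits a constant offset of a couple of millimetres.

`render_tunnel_mask()` scan-converts the corridor outline (offset curves of
the centreline plus semicircular end caps) with an even-odd rule; pixel
`(i, j)` covers the physical square centred at `((j-0.5)/res,
(i-0.5)/res)` relative to the plate corner.

### Camera occlusion

Walls of height `h` hide a strip of floor behind them. Under a pinhole
camera at height `H` over the plate centre, a wall top edge at lateral
distance `r` shadows a strip of radial width `r*h/(H - h)` on its far side.
`occluded_floor_fraction()` integrates this along the corridor. For the
default geometry (5 mm walls, 700 mm camera) the model yields about 7 % of
hidden floor, concentrated towards the outer turns (the per-bin profile and
its correlation with `|s|` are reported). Two remarks: the strip model
counts every hidden point of bare floor, which is the most pessimistic
reading — an organism of finite body size can only disappear completely
where the strip is wider than its body (`object_diameter` reduces each strip
accordingly and yields a far smaller fraction, consistent with the
observation that only ~1 % of individuals are typically concealed);
and photographic estimates of the monitored surface tend to be more
optimistic than the geometric model because the bright wall flanks blend
into the corridor in a thresholded image.

## Synthetic data

The generator is first-class, tested code: dispersal along the corridor is a
reflected Gaussian random walk in `s` with a piecewise-constant diffusion
coefficient (`dispersal_model()`), and `render_sequence()` embeds the
walkers into the plane (uniform lateral jitter of `path_width/3`), paints
each as a dark soft-edged ellipse of aspect 2.5 oriented along the corridor,
multiplies the scene by an illumination field (horizontal gradient of 14 %
plus a mild vignette, emulating a large LED panel), and adds Gaussian pixel
noise. A configurable 1 % of individual-frames is marked invisible,
emulating concealment behind walls. Every frame is reproducible in
isolation from the seed.

The three built-in phase schedules (`dispersal_preset()`) express the
canonical qualitative dynamics over a six-hour assay: `type1` — constant
D = 10 mm²/min; `type2` — latency (D = 2, 135 min) then sustained fast
spread (D = 20); `type3` — latency (D = 2, 120 min), fast phase (D = 25,
120 min), then a slowdown (D = 5). The coefficients are package defaults
chosen so phases are clearly separated while the group stays well inside a
maze of a metre or more; all individuals switch phases synchronously (a
deliberate simplification — no individual-level switching model is
implied by the data the package targets).

What the generator does *not* emulate: optics (point-spread, motion blur),
host-egg interactions, flight or jumps, and individual heterogeneity in
mobility. Passing the simulation studies therefore demonstrates that the
pipeline is internally consistent on diffusive ground truth, not that any
particular organism diffuses.

## Detection

Frames are processed in packs of 60 (configurable): within each pack the
still background is the per-pixel temporal median (robust against moving
particles; the mean is available), each frame is subtracted from it in
floating point so the dark insects give positive signal, the difference is
thresholded (fixed grey-level threshold, 50 by default) and 8-connected
components are measured. Descriptors follow the conventions of the common
particle-analysis tools: circularity `4*pi*area/perimeter^2` with a Moore
chain-code perimeter (diagonal steps weighted `sqrt(2)`), solidity as the
fraction of the convex hull's lattice pixels covered, aspect ratio from the
moments-equivalent ellipse. Detection is invariant to global additive
illumination changes by construction.

## Skeleton fragmentation and the curvilinear coordinate

The corridor mask is thinned (Zhang-Suen, followed by removal of redundant
simple pixels so the skeleton is a genuine 1-px 8-connected curve), spur
branches shorter than the corridor width are pruned, and the resulting open
curve is cut wherever it crosses a square grid (default spacing: half the
corridor width). The fragment chain is anchored at the intersection of the
diagonals of the mask's bounding rectangle; `s = 0` is the nearest skeleton
point, the arm leaving the centre towards +x carries positive `s`.

Cumulative arc length is measured on chords between skeleton pixels about
half a grid cell apart rather than by counting unit/`sqrt(2)` steps: the
naive 8-connected step count overestimates digitized curve length by ~5 %
on average, which would translate into centimetre-scale coordinate errors
at the arm tips; chord subsampling brings the skeleton length within a few
tenths of a percent of the generating centreline. Detections are projected
orthogonally onto the two skeleton segments adjacent to their nearest
skeleton pixel (bucketed nearest-neighbour search), giving `s`, the
perpendicular offset, and the fragment index; the projection is exact, the
fragment-quantized coordinate is available from the fragment table.

## Filtering

Four pure predicates, applied in a fixed order for reporting purposes
(membership is order-independent): *redundancy* — a rounded position (2 px
tolerance) recurring in more than half of all frames is a static artifact
and all its detections are removed; *area* bounds; *edge* — perpendicular
offset above 90 % of the corridor half-width (wall shadows); *circularity*
below 0.4 (streaks). The area and circularity defaults derive from the
rendered insect size, and all thresholds are configuration values.

## MSD, phase structure, classification

`msd_series()` is the plain per-frame mean of squared arc distances from the
release point, with unlinked detections as the sampling unit.
`window_average()` produces the 15-min averaged series (360 min -> 24
points) used for reporting and for the piecewise regressions, and
`acf_lag1()` implements the residual lag-1 autocorrelation check.

Two statistical facts shape the analysis of a *single* assay, and both are
easy to miss:

1. **MSD errors are serially correlated.** The same individuals are measured
   at every time point, so the MSD's sampling error drifts like a random
   walk. An ordinary F-test comparing segmented fits of the MSD *levels*
   treats these drifts as structure: in simulations with 200 diffusive
   walkers it rejects the true linear model four times out of five. The
   increments of the MSD between window boundaries, by contrast, are
   martingale differences — uncorrelated — with H0 variance proportional to
   `(2t + h)`. `classify_msd()` therefore fits piecewise-constant growth
   rates to the boundary increments (boundary values averaged over ±7 min
   to damp detection noise) by weighted least squares with exhaustive
   search over jump locations, and calibrates the two selection-adjusted
   sup-F tests (0 vs 1 vs 2 phases, 2 parameters per added phase, alpha =
   0.05) by parametric bootstrap whose noise carries the small MA(1)
   correlation the boundary averaging induces (lag-1 ≈ 0.14, measured once
   under the diffusive null and frozen). The second-jump test uses
   jump-robust local variance estimates (rolling median of squared
   successive differences), because a slope change also changes the
   increment variance and a slow final phase is far more precise than a
   global time-scaling suggests.
2. **The release clump censors the centre.** A group released at a point
   overlaps for a long time; per-frame particle analysis merges touching
   blobs, so central detections are missing and the plain MSD is biased
   upward early on — enough to fake phase changes. The upper order
   statistics of `|s|` are immune: the m-th largest distance among
   detections equals the m-th largest among all released individuals as
   long as the sparse tails resolve. `robust_msd_series()` matches the
   ranked tail (ranks 5-15 % of the released count) to folded-normal
   order-statistic means, optionally weighting detections by their
   area-estimated multiplicity so that merged pairs still advance the rank
   count. The classifier runs on this series in the full pipeline; the
   plain series remains the estimator of record for sparse scenes.

The levels-based machinery the field expects is implemented exactly as
usual — `fit_piecewise()` (continuous hinge model, exhaustive breakpoint
grid at a quarter of the time step, OLS conditional on the breakpoints,
deterministic global optimum) and `classify_dispersal()` (nested F-type
LRTs) — and is the right tool for replicate-averaged series whose errors
are independent across time.

Dispersal labels follow the slope patterns: no significant breakpoint =
`type1` (diffusive); one breakpoint with a faster second phase = `type2`;
two breakpoints with slow-fast-slow = `type3`; any other pattern =
`other`.

## Validation statistics

`detection_rate_ci()` (exact Clopper-Pearson binomial interval),
`chi2_homogeneity()` (2 x k contingency test of detected vs true spatial
distributions, df = k - 1), `skewness_symmetry_test()` (two-sided
Monte-Carlo test of sample skewness against a Gaussian null),
`per_minute_screen()` (per-minute ANOVA or skewness screens with Bonferroni
correction over minutes), and `variance_partition()` (sequential-ANOVA
share of the strain term, `SST(strain) / (SSR + SST(strain) +
SST(other))`).

## Problem sizes used by the simulation studies

The test-suite studies run on a reduced arena, `demo_maze()` (220 x 165 mm,
~1.25 m corridor, identical proportions), imaging a 2 mm organism at
2-2.5 px/mm so that body size is ~5 px, as it would be for a 0.5 mm insect
at 16 px/mm on the full device. The dispersal-type recovery study uses 30
rendered assays per type (200 individuals, 360 frames each); estimator
calibrations use simulation-only batches of 50-2000 runs. These sizes are
the package's own choices for its reference studies.

## Known limitations

* The quantile MSD estimator assumes near-Gaussian spread (true for the
  reflected random walk away from the tips); heavy-tailed kernels would
  need different rank calibration.
* Breakpoints from the increment classifier are reported at window-boundary
  resolution (15 min by default); use `fit_piecewise()` on the averaged
  levels for sub-window refinement.
* No trajectory linking: quantities that need identities (per-individual
  speeds, pauses) are out of scope.
* The occlusion model treats walls as opaque vertical planes and reports
  bare-floor shadowing; translucent walls scatter light into the shadow
  strips in real devices.
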