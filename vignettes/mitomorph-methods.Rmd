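---
title: "Quantifying mitochondrial distribution and transport in neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial distribution and transport in neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Neurons position mitochondria along dendrites and axons through active,
motor-driven transport, and failures of that transport reshape both the
organelle distribution and, over development, the dendritic arbor itself.
This package implements the measurements used to quantify those phenotypes
from standard imaging data: traced morphologies (SWC), two-channel still
images (an organelle label plus a cell fill or dendritic marker), and
time-lapse movies of labelled organelles moving along a process. Every
statistic has a synthetic-data generator counterpart with exact ground
truth, so the whole chain is testable without microscopy data.

```{r setup}
library(mitomorph)
```

## Morphometry of traced cells

A `neuron_morphology` is a validated rooted tree of nodes in micrometers.
From it the package computes total dendritic (and axonal) cable length,
branchpoint counts, Sholl profiles, and a size-normalized branchpoint
statistic:

* **Sholl profiles** use concentric spheres centered at the soma centroid at
  radii `step, 2 step, ...`. Intersection profiles count process crossings
  per sphere; branchpoint profiles count branchpoints per annulus
  `[r, r + step)`.
* **BP90** divides each branchpoint's radial distance by the cell's maximum
  radial tip distance (tip = 1) and reports the interpolated 0.90 quantile.
  It is invariant to rigid motion and uniform scaling, which makes cells of
  different sizes comparable; smaller values mean branching concentrated
  near the soma.

```{r}
cell <- generate_tree(tree_model(seed = 1))
morphometry_summary(cell)
```

Two conventions matter and are applied consistently:

* **Radial, not path, distance** is the default for Sholl, BP90 and the
  mitochondrial probability map, matching the geometry of shells radiating
  out from the soma. Path (arclength) distance is available as an option for
  branchpoint profiles, and is always used where the measurement runs along
  a process (occupancy gaps, axonal density).
* **Half-open shells**: a point exactly on a shell edge belongs to the outer
  annulus, and a segment whose endpoint lies exactly on a sphere still
  counts as crossing it. This makes every boundary case deterministic.

The quantile behind BP90 uses linear interpolation between order statistics
(`stats::quantile`, type 7); the estimator was left continuous in the data
rather than a step function so that small coordinate perturbations cannot
move the statistic by a whole order statistic.

Whether size normalization should use the longest tip per cell or a
per-dendrite reference is genuinely open; the per-cell maximum tip distance
was chosen because it keeps the statistic a single number per cell and makes
the scaling invariance exact. Soma centers are the centroid of the
soma-labelled nodes, overridable for single-point somas.

## Mitochondrial distribution

The pixel-shell profile (`mito_sholl`) counts thresholded organelle-channel
pixels per one-pixel-wide annulus around the soma — the finest radial
resolution the image supports. Integrating and normalizing gives the
**mitochondrial probability map** (MPM): the cumulative fraction of
mitochondrial mass within a normalized distance from the soma, where 1 is
the dendritic tip, *not* the farthest mitochondrion — a distinction that
matters precisely when mitochondria fail to reach the periphery.
**Mito60** is the normalized distance at which the MPM first reaches 60%,
linearly interpolated between grid points (an exact 0.60 at a grid point
returns that point). Uniformly distributed mass gives 0.6; proximal
accumulation gives smaller values.

```{r}
ms <- place_mitochondria(300, placement_model("uniform",
                                              n_mitochondria = 2000),
                         seed = 1)
mito60(mpm(position_profile(ms, 1), 300))
```

Supporting statistics:

* **Mitochondrial index**: organelle foreground area over dendrite-marker
  foreground area in a region; organelle pixels count only where they
  overlap the dendrite mask, so somatic or axonal signal cannot inflate it.
* **Occupancy gaps**: the path is sampled at `step` = 0.1 um (midpoints of
  sampling cells, well below optical resolution) and a sample is occupied if
  a mitochondrial footprint covers it; the capture radius in mask mode
  defaults to 0.5 um, about an organelle radius at these magnifications.
  Both are configurable.
* **Axonal density** (`10 * count / length`) and length-normalized
  **relative positions** for pooled axon plots.

Thresholding defaults to Otsu's criterion, which assumes the foreground and
background populations are comparable in size. On channels where the signal
occupies a percent or less of the field Otsu collapses onto the background
noise; such channels should be segmented with a fixed threshold (the
segmentation tests cover both regimes). Which thresholding the original
pixel-shell analyses used is not recoverable; Otsu is a default, not a
claim.

## Trafficking from kymographs

`build_kymograph` samples each frame at unit arclength along a traced path,
taking the maximum over `line_width` perpendicular offsets, producing the
classical space x time image: stationary organelles are horizontal bands,
transported ones sloped lines. `detect_and_link` finds per-frame 1-D local
maxima (parabolic sub-pixel refinement) and links them greedily by nearest
neighbour, rejecting jumps beyond `max_jump`; tracks shorter than 3 frames
are dropped.

Three decisions here are worth making explicit:

* **Mobility threshold.** A track is mobile when its net displacement over
  the movie reaches 2 um, the conventional cutoff in the axonal-transport
  literature; over a 2-minute movie, slower net drift is indistinguishable
  from stage noise. Ties count as mobile.
* **Greedy linking with a short gap allowance.** Global assignment is
  unnecessary at the particle densities of dendritic organelles, and greedy
  linking keeps the algorithm transparent. Two particles closer than the
  optical resolution merge into a single detection for a frame or two, so a
  track may coast for `max_gap` (default 1) missed frames before being
  retired; without this, every sub-resolution encounter splits a trajectory
  and the motile fraction is biased upward. Crossing traffic can still swap
  identities — a documented limitation of greedy linking.
* **Per-run velocities.** Consecutive same-direction steps above a noise
  floor (default one pixel-equivalent per frame, the scale of sub-pixel
  detection jitter) form runs; each run reports distance over duration, and
  pauses are excluded. Summaries average over runs, not tracks, so a long
  run contributes proportionally to its duration.

Direction is oriented by which end of the path faces the soma
(`soma_end`); flipping it swaps anterograde and retrograde exactly, which
the tests assert through the full pipeline.

## What the generators emulate — and what they do not

`generate_tree` grows planar trees from a soma: branch events form a
Poisson process along cable length (`branch_rate` per um), branches
terminate at a truncated-Normal segment length, and direction follows a
random walk (`tortuosity` radians per um step). Defaults (5 primaries,
0.015 branchpoints per um, 80 +/- 30 um segments, depth 7) are sized to
resemble a two-week cultured pyramidal cell: a few thousand um of dendrite
with a few dozen branchpoints.

`place_mitochondria` draws normalized positions from a uniform or
truncated-exponential density, the two regimes contrasting a healthy
homogeneous distribution with proximal accumulation when transport fails
(`tau` = 0.3 is used as the accumulated condition throughout). On a tree, a
root-to-tip path is chosen with probability proportional to its tip
distance and the mitochondrion sits at the drawn fraction of that tip's
distance, so the ground-truth normalized coordinate is exactly
density-distributed for any topology — this is what makes the closed-form
Mito60 oracle (`x = -tau log(1 - 0.6 (1 - e^(-1/tau)))`) exact.

`simulate_timelapse` assigns mobility by a Bernoulli draw, a direction, a
personal speed, and alternates runs and pauses with exponential waiting
times; particles reflect at the path ends so the particle count stays
constant. Frames are rendered as Gaussian spots plus Gaussian camera noise.

These generators deliberately omit: 3-D arbors and confocal sectioning,
uneven illumination and photobleaching, organelle fission/fusion, motor
kinetics and microtubule polarity, and calcium-dependent stopping. Passing
parameter-recovery tests therefore demonstrates the correctness of the
measurement chain, not robustness to every artifact of real microscopy.

## Numerical choices and test scales

* Mito60/BP90 interpolation is linear and anchored at (0, 0); degenerate
  inputs (no branchpoints, zero mitochondrial mass, zero dendrite area)
  raise errors rather than returning 0, because the undefined and the
  proximal cases must not be conflated.
* Mann-Whitney p-values are exact by full enumeration of group assignments
  for pooled n of at most 20 (midranks make this valid under ties) and use
  the tie-corrected normal approximation beyond; Welch's form is used for
  t-tests. Group curves (Sholl, MPM) are averaged on a common grid, which
  preserves monotonicity and the endpoint of cumulative curves.
* All generators consume an explicit seed and are byte-reproducible.

The test suite runs at sizes chosen to make sampling error a small fraction
of each tolerance: 2000 placements per cell for the analytic Mito60
recoveries (empirical-quantile sd about 0.011, so the uniform check
averages 10 seeds); cohorts of 15 cells for the group discrimination; and
200 particles per condition — 40 movies of 5 particles on 200-um paths, 60
frames at 2 s, 0.1 um pixels — for trafficking recovery, where the binomial
sd of the realized motile fraction (about 3.5 points at p = 0.6) is the
dominant term inside the 5-point recovery band. The three motile-fraction
conditions share one movie seed set, a paired design that removes
between-condition seed noise from the comparison.

## Limitations

Analyses are 2-D; z coordinates participate in distances but shells are
radial, so heavily 3-D arbors projected to 2-D will mix radii. Greedy
linking is not suitable for dense or frequently crossing traffic. The
mitochondrial index and occupancy statistics depend on segmentation
quality; with sparse signal, fixed thresholds calibrated on controls are
more reliable than Otsu. Multi-group statistics (ANOVA and nonparametric
analogues with post hoc corrections) are out of scope: the package exposes
two-group contrasts only, and the CSV outputs are designed to feed external
statistics tools where more is needed.
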