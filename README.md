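# mitomorph

Neurons depend on active transport to place mitochondria along their
dendrites and axons; when transport fails, mitochondria pile up near the
soma, distal dendrites empty out, and the dendritic arbor itself remodels.
`mitomorph` is an R package for quantifying these phenotypes from standard
imaging data — SWC morphology traces, two-channel still images
(mitochondrial label + cell fill / dendritic marker), and time-lapse movies
of labelled organelles — aimed at labs doing neuronal cell biology and
organelle-transport genetics.

## What it computes

**Morphometry** (from SWC traces): total dendritic and axonal cable length,
branchpoint counts, Sholl profiles (intersections per sphere or
branchpoints per annulus at radii *r*, 2*r*, …), and **BP90** — the
interpolated 0.90 quantile of branchpoint distances after dividing by the
cell's maximum tip distance, so cells of different sizes are comparable.

**Mitochondrial distribution**: the pixel-shell radial profile of a
thresholded mitochondrial channel (foreground pixels per one-pixel annulus
around the soma), its normalized integral the **mitochondrial probability
map** MPM(x) = fraction of total mitochondrial mass within normalized
distance x (tip = 1), and **Mito⁶⁰** = min{x : MPM(x) ≥ 0.60} — 0.6 for a
uniform distribution, smaller under proximal accumulation. Also the
mitochondrial index (mito area / dendrite-marker area), occupancy gaps
(fraction of dendritic length with no mitochondrion footprint), mitochondria
per 10 µm of axon, and length-normalized positions.

**Trafficking**: kymograph construction along a traced path (space × time,
maximum over a perpendicular line width), particle detection with sub-pixel
refinement, greedy nearest-neighbour linking, and per-cell summaries —
percent mobile (net displacement ≥ 2 µm by default), the
anterograde/retrograde split among mobile organelles, and mean per-run
velocities with pauses excluded.

**Synthetic data with ground truth**: stochastic dendritic trees (Poisson
branching along cable), mitochondrial placements from uniform or
truncated-exponential densities (density ∝ e^(−x/τ) on [0, 1]; the Mito⁶⁰
of such a placement has the closed form −τ·ln(1 − 0.6(1 − e^(−1/τ)))),
two-channel rasterization with PSF blur and noise, and run-and-pause
time-lapse simulations. Every analysis stage has a parameter-recovery test
against these generators.

**Statistics**: Welch t-test and Mann-Whitney (exact by full enumeration
for pooled n ≤ 20, handling ties; tie-corrected normal approximation
beyond), and reference-relative percent change.

## Worked example

```r
library(mitomorph)

# a synthetic cell with proximally accumulated mitochondria
cell  <- generate_tree(tree_model(seed = 42))
morphometry_summary(cell)
#>   total_dendritic_length total_axonal_length n_branchpoints
#> 1                   3284                   0             27
#>   n_primary_dendrites      bp90
#> 1                   5 0.5902082

mitos <- place_mitochondria(cell,
  placement_model("truncated_exponential", tau = 0.3, n_mitochondria = 300),
  seed = 42)
mito60(mpm(position_profile(mitos, 1),
           max_tip_distance(cell, mode = "path")))
#> [1] 0.164

# trafficking in a simulated 2-minute movie
mm  <- motility_model(p_mobile = 0.3, seed = 42)
sim <- simulate_timelapse(200, mm, n_frames = 60, frame_interval = 2,
                          pixel_size = 0.1, n_particles = 5, noise_sd = 2)
ky  <- build_kymograph(sim$stack, sim$path, pixel_size = 0.1,
                       frame_interval = 2)
summarize_motility(detect_and_link(ky, detection_threshold = 30,
                                   max_jump = 2), noise_floor = 0.15)
#> <motility_summary> 5 tracks; 20.0% mobile (0% antero / 100% retro)
#>   mean run velocity: antero NA um/s, retro 0.408 um/s
```

The cell's 3284 µm of dendrite and 27 branchpoints are in the range of a
cultured pyramidal cell; its BP90 of 0.59 says 90% of branchpoints sit
within 59% of the distance to the farthest tip. The Mito⁶⁰ of 0.164 —far
below the uniform value of 0.6 — reflects the proximal accumulation built
into the τ = 0.3 placement. In the movie, 1 of 5 mitochondria moved more
than 2 µm net, retrograde, at 0.41 µm/s per run, close to the simulated
0.4 µm/s run speed.

A thin CLI over the same functions is in
`inst/scripts/mitomorph-cli.R` (subcommands `morphometry`, `simulate`,
`compare`); batch workflows are `run_morphometry()` and `run_mitomap()`,
which write per-cell CSV tables and group-averaged Sholl/MPM curves.

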