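---
title: "Quantifying the epidermal wound response: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the epidermal wound response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`woundwave` quantifies the rapid, coordinated response of the larval
zebrafish epidermis to tailfin wounding from two-channel fluorescence
timelapses: how fast basal cells move, how waves of calcium activity and of
migration propagate away from the wound, how actin reporter intensity
changes once tissue deformation is factored out, how much cells swell, and
how the wound's electrical circuit behaves under stimulation. This vignette
is the package's own account of each method, its assumptions, the tunable
parameters, and what the synthetic-data validation does and does not show.

## The analysis chain at a glance

1. **Container** (`timelapse_stack`): a calibrated `T x Z x C x Y x X`
   array with µm/px, µm/z-step and s/frame metadata. Coordinates are
   1-based pixel centers, `x` = column, `y` = row; all reported distances
   are µm, speeds µm/min.
2. **Rigid registration** (`mask_reference_channel`,
   `estimate_rigid_track`, `apply_rigid_track`): whole-body drift removed
   using a ubiquitous reference channel after zeroing skin-derived signal.
3. **Velocimetry** (`track_features`, `speed_kymograph`): sparse corner
   tracking reduced to a distance-from-wound vs time kymograph.
4. **Intensity dynamics** (`gcamp_kymograph`, `demons_field`,
   `warped_dff_trace`): reference-normalized ΔF/F0 in space-time bins, and
   pixelwise ΔF/F0 decoupled from tissue deformation by non-rigid warping.
5. **Volumetry** (`richardson_lucy_3d`, `build_height_map`,
   `integrate_volume`): cluster volume as the integral of a two-surface
   height map.
6. **Statistics** (`pca_trajectories`, `welch_anova`, `games_howell`,
   `paired_ttest_d`, `bootstrap_ci_mean`): the trajectory-level inference
   layer.
7. **Biophysics** (`fit_binding_curve`, `circuit_solve`,
   `current_density`): closed-form models for the sodium calibration and
   the stimulation circuit.

Every module is exercised end to end on seeded synthetic microscopy from
the generator functions (`make_sheet_timelapse`, `make_calcium_timelapse`,
`make_cluster_stack`, `make_calibration_images`), which emit a
`GroundTruth` sidecar carrying the analytic truth.

## Rigid registration

Whole-larva drift is estimated on the reference (myosin-like) channel.
Skin-derived fluorescence is first suppressed: the signal channel's
per-frame z-projection is thresholded (Otsu by default; the threshold
method and value should be logged per run since different datasets need
different choices) and the corresponding reference voxels zeroed, so
structures that do not move with the migrating skin dominate.

Corner features with normalized 11×11-pixel patch descriptors are matched
between adjacent frames (nearest neighbour, Lowe ratio 0.75), and a
Euclidean transform (rotation + translation) is fitted by RANSAC (residual
threshold 2 px, 1000 seeded iterations, minimum 8 inliers) followed by a
least-squares Procrustes refit on the inliers. Frames with too few matches
are flagged and carry the identity. Cumulative transforms map every frame
into frame-1 coordinates; resampling is bilinear and out-of-bounds pixels
become `NA`, never silent zeros. Corner positions are refined to sub-pixel
by a parabolic fit of the corner response; without this the per-frame
transforms quantize at ~0.1 px and the self-registration fixed point
(re-registering a registered stack yields identity within 0.1 px / 1e-3
rad) is not reachable.

*Assumption*: drift is rigid in-plane (rotation + translation). Slow
non-rigid body deformation leaks into the downstream velocity field; the
relative-velocity correction (below) is the mitigation.

## Feature-point velocimetry

Shi-Tomasi corners (quality 0.01 of the strongest response, minimum
separation 5 px, 3×3 structure-tensor window) are tracked with a pyramidal
Kanade-Lucas-Tomasi tracker: 15×15 px window, 3 pyramid levels, up to 30
iterations per level. A forward-backward check re-tracks each point to its
origin and kills tracks deviating more than 1 px; displacements above 20
px/frame are rejected as physically implausible. Corners are re-detected
every 10 frames and merged in (new tracks inherit no history), offsetting
track attrition.

Velocities come from central differences of track positions (one-sided at
track ends). The wound axis runs from the wound centroid toward the
centroid of all tracked points; a point's 1D coordinate is its projection
on this axis, in µm from the wound. Points are binned every 10 µm by their
current-frame coordinate (binning by first-frame coordinate is the
`bin-by-birth` alternative a caller can implement from the same tracks;
current-frame binning keeps bins attached to tissue locations as the sheet
contracts). The kymograph records the **mean of per-point 2D speed
magnitudes** per bin and frame — not the magnitude of the mean velocity —
so incoherent motion registers as nonzero speed; the `horizontal` variant
averages the signed x component instead, for stimulation experiments where
anterior/posterior sign matters. Empty bins are `NA`, never 0.

Two corrections mirror experimental practice:

- `relative_velocity_correction`: the mean velocity vector of points
  beyond 300 µm from the wound is subtracted from every near-field point's
  velocity before speeds are computed, removing residual whole-larva
  drift that rigid registration missed.
- `mean_speed_trace`: the occupancy-weighted mean speed over bins within
  300 µm, over the first 30 frames (15 min), gives the per-larva speed
  trajectory used by the statistics layer.

**Front-speed estimation.** Wave speeds are read off a kymograph as the
slope of the half-maximum front: per frame, the farthest bin above half
the global maximum; then a Theil-Sen fit of front position vs time (robust
to single-frame dropouts; R² < 0.5 flags a non-advancing front). Frames in
which the detected front has reached the far edge of the field are
censored — beyond that point the measured position saturates at the field
boundary and no longer tracks the true front, which would otherwise bias
the slope low.

## ΔF/F0 intensity dynamics

**Calcium kymograph.** Pixels are binned by horizontal distance to the
wound centroid (10 µm). Per bin and frame, mean GCaMP intensity is divided
by mean nuclear-reference intensity, cancelling expression variation; the
ratio is then expressed relative to its own pre-wound baseline:
`ΔF/F0 = (F_t − F_0)/F_0`, with `F_0` the mean of the normalized signal
over the pre-wound frames (using the mean rather than a single frame
halves baseline noise; both conventions agree on noiseless data). Bins
with non-positive reference intensity are missing. ΔF/F0 is invariant to
any global gain by construction.

**Shape-decoupled actin intensity.** Reporter intensity changes are
confounded by cell deformation: a pixel brightens when cell material
converges on it. The package separates the two by non-rigidly aligning
every frame back to frame 1 and only then forming the intensity ratio.
The displacement field comes from a demons registration (3 multiresolution
levels, 50 iterations per level, Gaussian smoothing σ = 1 px of both the
per-iteration update and the accumulated field, updates combined by
composition). Two numerical choices matter:

- Both images are normalized to unit mean before iterating, so the field
  explains *shape*, not illumination. A movie with a global 10%
  brightening and no motion must yield a zero field and a ΔF/F0 trace of
  exactly 0.10 — with raw intensities the demons force would convert the
  brightness change into spurious displacement.
- The demons force uses Gauss-Newton-like damping with a self-scaling
  term: the damping matches the squared gradient at the rms residual,
  which caps each update near half the typical remaining displacement.
  The classic unit-length damping converges too slowly at texture scales
  of a few pixels.

Per-step fields are composed (`u_{1←t+1}(x) = u_{1←t}(x) + u_t(x +
u_{1←t}(x))`) so each frame warps directly onto frame 1. After warping,
frames are smoothed (Gaussian σ = 2 px), ΔF/F0 is computed pixelwise
against the smoothed first frame, and the spatial mean excludes: pixels
within one cell diameter (default 20 µm) of the wound polygon, where
margin cells deform too strongly for the warp to be trusted; pixels with
undefined warps; and pixels with non-positive baseline. On pure-motion
phantoms the trace stays within ±0.05 at every frame — this is the
decoupling contract the module exists for.

**Illumination QC.** Movies with flickering illumination are excluded on
two background-trace rules: least-squares slope > 0.005·m intensity units
per frame, or a first-frame deviation from m of more than 0.5·m, where m
is the movie's median background (typically a few hundred intensity
units; everything is normalized to the first frame, so a deviant first
frame poisons the whole trajectory). The default background region is the
darkest 5% of pixels of frame 1; supply a mask when the field of view has
no clean background.

## Height-map volumetry

Cluster volume is the integral of a per-pixel height map:

1. Richardson-Lucy deconvolution, 20 iterations, with a separable Gaussian
   PSF (defaults σ lateral 0.3 µm, axial 0.8 µm — an analytic stand-in for
   a spinning-disk PSF); FFT convolution with replicate padding. RL
   preserves non-negativity and conserves interior flux (checked to 1%).
2. Footprint mask: threshold on the max-intensity z-projection, largest
   connected component, holes filled. The default threshold is the robust
   half-max midpoint (between the 1st and 99.9th intensity percentiles)
   because the 50% contour of a blurred step sits at the true object
   edge; Otsu on these strongly bimodal projections lands well above half
   maximum and erodes the footprint by 5–10%, a direct volume bias.
3. Height per pixel: the stack is smoothed with a 3D Gaussian (σ = 1
   voxel) and edge-enhanced by a z-axis Sobel ([1 2 1] smoothing laterally,
   central difference axially) — the axial gradient is what turns the two
   cluster surfaces into two linescan peaks. The two dominant peaks (min
   separation 2 z-steps) are each refined by a Gaussian fit (log-quadratic
   over ±2 voxels); height = peak separation × z-step. Pixels with fewer
   than two peaks are flagged and later interpolated; more than 50%
   undefined aborts the map as unreliable.
4. Heights are computed on a stride-2 grid for speed, median-filtered
   (3×3) against single-pixel outliers, and bilinearly interpolated to all
   mask pixels (nearest-value fill at the rim).
5. `integrate_volume` sums height × pixel area (1 pl = 1000 µm³);
   `volume_trace` normalizes to the pre-wound frame and flags any frame
   whose volume jumps by more than 25% — the automated stand-in for manual
   screening of miscalculated maps.

On noiseless PSF-blurred phantoms the pipeline is accurate to ~5%
(hemisphere, slab, ellipsoid); residual bias is dominated by deconvolution
ringing pulling the surface-gradient peaks slightly inward (≈ half a
z-step) and by footprint discretization. Both biases are common mode
between timepoints, which is why *relative* volume — the quantity of
biological interest — is recovered to about one percentage point on a 50%
swelling phantom.

## Statistics layer

Per-larva speed trajectories (30 frames, 15 min) are analysed by
covariance PCA after subtracting the ensemble-mean trajectory — no
per-dimension scaling, since all 30 dimensions share units. Component
signs follow a fixed convention (largest-magnitude loading positive) so
scores are comparable across runs. On ensembles varying mainly in response
amplitude, PC1 score tracks amplitude (|r| > 0.95 in the validation).

Group comparisons use Welch's heteroscedastic ANOVA (variances between
wounding conditions differ strongly), with Games-Howell post-hoc pairwise
tests: Welch-type pairwise t statistics referred to the studentized range
distribution (`ptukey`) with Welch-Satterthwaite degrees of freedom. Under
unequal-variance nulls the Welch test's type-I error stays in [0.03,
0.07] at α = 0.05 (5000-replicate simulation in the test suite) — the
property that motivates choosing it over classical ANOVA.

Two effect sizes are reported because the source analyses use both: for
independent groups, `d = Δmean / sqrt((var_a + var_b)/2)` (average-variance
definition); for paired designs, `d = mean(diff)/sd(diff)` alongside the
paired two-tailed t-test. Confidence intervals are percentile bootstrap
(10^4 resamples, seeded; BCa was not used by the source workflow and the
percentile method is exactly reproducible), and
`paired_estimation_summary` packages the mean paired difference with its
bootstrap distribution and a kernel-density summary for estimation plots.

## Biophysics

**Sodium calibration.** Droplet images of an indicator at known NaCl
concentrations are background-subtracted and flat-field corrected
(`background_flatfield_correct`; the flat field is normalized to unit
mean), then mean intensities are fitted to the saturation binding curve
`I = I_max·[Na]/(K_d + [Na])` by Levenberg-Marquardt with positivity
bounds and a fallback grid of starting points. The inverse map
`[Na] = K_d·I/(I_max − I)` converts corrected intensities to
concentrations and refuses intensities at or above `I_max`. Fits where the
K_d standard error exceeds the estimate are flagged — this happens
whenever the sampled concentrations stay far below K_d (the curve is then
locally linear and only `I_max/K_d` is identified). Note that 5%
multiplicative intensity noise propagates to roughly 10% median error on
K_d even with a well-spread design: I_max and K_d are strongly correlated
when the curve is sampled only to ~2 K_d.

**Stimulation circuit.** The setup is modelled as series resistances —
electrodes (18.5 MΩ as measured reference), larva (~11 MΩ), a 100 kΩ
current-sensing resistor — with an optional shunt in parallel with the
larva (infinite by default: the assumption that no current bypasses the
larva). A measured total resistance (30.9 MΩ) may override the component
sum, with the residual attributed to unmodelled contact resistance; the
solver completes current ↔ voltage via Ohm's law, returns per-component
voltage drops (which must sum to the applied voltage), the larval current
under a finite shunt (current divider), and the fraction of applied
voltage dropping across the larva (≈ 35% for the values above — most of
the applied voltage is lost in the electrodes). `current_density` converts
a current and cross-section to mA/cm², with an area-reduction factor for
the hypothesis that current flows only through interstitial spaces.

## The synthetic generators: what they emulate, and what they do not

All generators fan one global seed into independent per-stream sub-seeds,
so identical spec + seed is bit-identical and adding a generator never
perturbs another.

- **Cell sheet** (`make_sheet_timelapse`): a Voronoi tessellation with
  bright 1–2 px junction ridges over dim cytoplasmic speckle — junctional
  actin signal with trackable corners at cell vertices. A radially inward
  displacement wave `u(d, t) = A·exp(−d/λ)·g(t − d/v)`, `g` a Gaussian
  pulse in time (width 60 s), advects the texture; its leading edge is at
  `v·t`. Defaults mirror the study conditions: 0.65 µm/px, 30 s frames,
  wave speed 40 µm/min, amplitude 3 µm, decay length 600 µm (the response
  reaches across the several-hundred-µm field; source movies do not
  quantify the decay, so this is chosen for testability, not fish
  realism). A second channel of static blobs carries only the rigid
  drift, emulating deep non-migrating structures.
- **Calcium wave** (`make_calcium_timelapse`): a sigmoidal activation
  front (width 15 µm) leaving the wound margin at 200 µm/min after
  baseline frames, riding on a smooth random expression map shared with a
  constant nuclear channel so that the ratio cancels expression, with
  plateau ΔF/F0 = 1.5.
- **Cell cluster** (`make_cluster_stack`): hemisphere / ellipsoid / slab
  occupancy rendered with 2× supersampling, Gaussian-PSF blurred, Poisson
  noise; the second timepoint is scaled isotropically so the after/before
  volume ratio is exact by construction.
- **Calibration droplets** (`make_calibration_images`): per-concentration
  droplet images under a radial parabolic vignette and additive
  background, plus the matching flat-field image.

**What passing these tests shows** — that the algorithms recover known
truth under the stated imaging conditions (texture contrast, noise level,
wave shapes, PSF widths). **What they do not show** — robustness to real
tissue: out-of-plane motion, z-drift, photobleaching, wound debris,
heterogeneous expression beyond a smooth field, autofluorescence, or
non-Gaussian PSF tails. Parameters quoted above are generator defaults,
not measurements of larval tissue.

## Numerical choices and degenerate inputs

- Bilinear interpolation everywhere; out-of-bounds samples are `NA` and
  are excluded from means rather than zero-filled.
- `tiff` stores pages on a 32-bit integer grid; `write_stack` scales by a
  power of two and records it, so integer-valued data (counts below 2^24)
  round-trips exactly and continuous data to ~2×10⁻¹⁰ of full scale.
- Theil-Sen (median of pairwise slopes) for front fitting: robust to a
  minority of mis-detected fronts, deterministic, no tuning.
- Demons declares divergence if the final dissimilarity exceeds the
  initial one beyond tolerance; identical images yield an exactly zero
  field.
- Degenerate guards with explicit errors: wound centroid coinciding with
  the points centroid; no far-field points for the relative-velocity
  correction; zero-variance groups in Welch's ANOVA; zero-variance paired
  differences; all-equal concentrations; intensities at or above I_max;
  non-positive volumes.

## Problem sizes used in the validation suite

The test suite and the acceptance script regenerate everything from code:
sheet phantoms of 160×300–260×560 px over 8–16 frames, calcium phantoms up
to 192×920 px (a 600 µm field at 0.65 µm/px), cluster stacks of ~50×120×120
voxels, 5000-replicate null simulations for the Welch calibration and
1000-replicate bootstrap-coverage checks. These sizes make the full
validation run in a few minutes on one CPU while keeping every recovery
criterion at the tolerances stated above.

## Known limitations

- KLT assumes brightness constancy; strong local intensity transients
  (e.g. the calcium wave itself) should be tracked on a structural
  channel, not the indicator channel.
- The demons field is 2D; axial motion appears as intensity change and is
  not decoupled.
- Height-map volumetry requires two resolvable surfaces; clusters thinner
  than ~2 z-steps plus the axial PSF are flagged as undefined.
- Games-Howell p-values rely on the studentized range distribution with
  non-integer degrees of freedom as implemented by `ptukey`; extremely
  small groups (n = 2) give conservative results.
- The circuit model is lumped; it cannot resolve spatial field
  distributions within the larva (that would need finite-element
  modelling, out of scope).
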