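---
title: "From swept B-scans to volumes: the bscan3d processing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From swept B-scans to volumes: the bscan3d processing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bscan3d)
```

## The problem

A conventional ophthalmic B-scan probe produces 2D cross-sections. Mounting
the probe on a linear actuator and translating it at constant speed across
the closed eyelid (or a test phantom) turns the probe's video output into an
implicit 3D dataset: each frame is a slice at a known elevation
`y = v * t`. Recovering an explicit volume from such a screen-captured sweep
requires undoing four acquisition artifacts:

1. **Container duplication.** Screen capture records at the display rate
   (e.g. 30 fps) while the probe refreshes its image more slowly; most
   recorded frames are repeats of the previous acquisition.
2. **Burnt-in annotations.** Scale bars, labels and crosshairs are painted
   over the echo data in every frame.
3. **Probe drift.** The probe can wander slightly in-plane during the sweep.
4. **Sector distortion.** Sector (fan) probes display scan lines
   radius-by-angle; a physically flat reflector appears curved, and
   eccentric features appear tilted, until the data are resampled onto a
   Cartesian grid.

`reconstruct_sweep()` chains the corrections — deduplicate, remove overlay,
register, scan-convert, stack — and writes the result as NIfTI with the
voxel spacing and world origin in the affine.

## Stage models and their assumptions

### Deduplication

Two consecutive frames are "the same acquisition" when their mean absolute
intensity difference is at most a tolerance (default 0.5 levels on the 8-bit
scale — byte-exact equality fails on lossy captures, while genuinely new
B-scan content differs by far more than half a level). Retention is greedy
against the last kept frame, which makes the operation idempotent. Retained
frames keep their container timestamps; slice elevations are later computed
from those timestamps, so an irregular retention pattern cannot skew the
geometry. The derived `effective_rate` field uses
`(retained - 1) / (t_last - t_first)`.

### Overlay removal

Echo speckle decorrelates from frame to frame; a painted overlay does not.
Pixels whose temporal mean is in the top 1% (`intensity_quantile = 0.99`)
*and* whose temporal standard deviation is at most 1 level
(`sd_ceiling = 1`) are flagged, and connected components under 4 px are
dropped as coincidences. Both thresholds are exposed: overlay brightness and
capture compression vary across vendors, and the defaults were chosen from
synthetic-overlay recovery experiments in the test suite (crosshair recall
1.0, false-positive rate 0.0 under developed speckle). Masked pixels are
filled with the median of unmasked neighbors in a growing window (or zeroed
with `fill = "zero"`). Removal runs *before* registration by default,
because a bright static structure present in both frames pins the
correlation peak at zero shift; the reverse order is available
(`order = "register_first"`) for fidelity to chains that register first.

### Drift registration

"Linear registration" is implemented as translation-only alignment:
sequential frames of a linear sweep differ mainly by small in-plane drift,
and fitting rotation or scale to speckle risks chasing noise (the transform
family is deliberately restricted; rotation support would extend
`transform2d` without changing the contract). The estimator maximizes
normalized cross-correlation over integer shifts within `max_shift`
(default 10% of the frame), coarse-to-fine for large windows, on band-pass
filtered copies (Gaussian sigma 1 minus sigma 8): the high-pass removes DC
and residual overlay bias, the mild low-pass suppresses the pixel-locking
that otherwise biases subpixel estimates toward integers. The subpixel
refinement fits a parabola to the *logarithm* of the three correlation
samples around the peak — the peak of a correlation of band-limited texture
is locally Gaussian, and the log fit measured ~0.001 px bias against
Fourier-shifted ground truth versus ~0.01–0.02 px for the plain parabola.
That margin is what lets a cumulative drift of 0.25 px/frame be recovered
within 5% over a 2 s sweep.

Drift is corrected fully, with no detrending: the sweep motion is
out-of-plane, so any in-plane shift is treated as artifact. Registration
confidence (peak correlation) is reported per frame; independent noise
pairs score below 0.2, and the caller decides what to do with
low-confidence transforms.

### Scan conversion

A sector geometry maps pixel (row, col) to radius and ray angle linearly,
with the fan apex `apex_offset` mm above the first row:
`x = r sin(theta)`, `z = r cos(theta) - apex_offset`. Conversion inverts
this map per output pixel with bilinear interpolation; pixels outside the
fan are zero-filled and excluded via the validity mask rather than given a
sentinel intensity, so downstream noise statistics are not corrupted. When
a probe has no sector block in its config, the mapping is the identity —
the fallback for probes whose fan parameters are unpublished. The shipped
presets reflect this: the sector parameters of the two dedicated ophthalmic
probes are not public, so their presets are linear-array; the handheld
probe preset carries a representative (invented, clearly labelled) sector
so the correction path is exercised end to end.

### Elevation stacking

Slices are placed at `y = speed * (t_i - t_1)` and the volume is filled by
linear interpolation between neighboring slices; no extrapolation happens
beyond the first/last slice. Default voxel spacing is anisotropic and
faithful to the acquisition: the in-plane pixel spacing for x/z and the
median slice gap (`speed / rate`) for y. Linear blending cannot over- or
undershoot the slice intensities, and a voxel at an exact slice elevation
reproduces that slice. Validity masks from scan conversion and drift
correction are intersected and stored as a companion `_mask` NIfTI. The
NIfTI affine is diagonal RAS with axis order (lateral, elevation, depth).

## The simulator: what it emulates, what it does not

`rasterize_phantom()` builds three test objects: a planar bar grid, a bare
dome, and a dome carrying concentric rings plus radial spokes — by default
6 rings, 0.3 mm wide, 1.5 mm apart on a 12 mm-radius dome (ring count and
width match the physical resin phantom this family of phantoms emulates;
pitch, spoke count and radius are invented, eye-scaled defaults). Shell
surfaces are rasterized with a one-voxel soft edge: hard voxelization was
measured to inject more surface roughness than the genuine slice-spacing
steps at slow sweeps, inverting the speed ordering the metric exists to
detect.

`simulate_sweep()` renders the screen capture a probe would produce:
content refreshing at the native rate inside a faster container (duplicates
are byte-exact), separable Gaussian PSF (axial/lateral FWHM from the probe
spec), multiplicative Rayleigh speckle of configurable contrast, cumulative
in-plane drift, and an optional crosshair/scale-bar overlay composited
last. Speckle is *elevation-correlated*: seeded Rayleigh anchor fields are
blended with a decorrelation length defaulting to the lateral PSF width,
because overlapping beams in a real sweep share their interference pattern
— with independent per-frame speckle, surface-detection jitter at dense
slice spacing would swamp the geometric step artifact. Everything is
deterministic given the seed.

The echo model is interface brightness only: no attenuation, shadowing,
refraction, or wave propagation, and no elevation-direction PSF in the
rendered frame itself. Passing tests therefore demonstrate the *pipeline's*
correctness on data with realistic geometry, duplication, drift, overlays
and speckle statistics — not robustness to reverberation, motion during a
frame, or vendor post-processing found in clinical captures.

## QC metrics

- `noise_stats()`: mean signal and population SD over an ROI (default the
  central 50% crop — the usual "non-border" sampling region).
- `feature_centroids()` + `curvature_and_angulation()`: intensity-weighted
  centroids of thresholded components in physical mm, least-squares (Kasa)
  circle fit through them (curvature 0 reported for collinear sets,
  detected via the second singular value), first-to-last chord length, and
  per-feature principal-axis tilt. This quantifies the flat-grid curvature
  and eccentric-feature angulation artifacts of raw sector display; the
  acceptance suite requires scan conversion to reduce the fitted curvature
  at least 10-fold.
- `ring_profile_metrics()`: maximum-intensity en-face projection, angular
  average into a radial profile (bin width = the finer in-plane spacing),
  peaks by topographic prominence relative to the profile range (default
  0.2; the physical count was established visually, this makes it
  reproducible), and the median full width at half prominence. Distances
  are en-face by default; passing `dome_radius` converts to arc length
  along the dome surface, where the physical ring width is defined.
- `step_artifact_metric()`: depth of the first half-maximum threshold
  crossing per (x, y) column with subvoxel interpolation, a 5-voxel
  running mean along x (steps are elevation-axis structures constant
  across the frame, so lateral smoothing suppresses per-column speckle
  jitter without touching the staircase), then the RMS second difference
  of depth along the elevation axis, in mm. It is near zero for smooth
  dense reconstructions, scales linearly with staircase step height, and
  increases strictly with sweep speed at a fixed frame rate.

## Numerical choices and degenerate inputs

- Pixel indices are 1-based (R convention); frame offsets in the sweep
  kinematics are 0-based so frame 0 sits at y = 0.
- Bilinear interpolation tolerates 1e-6 of float overshoot at grid borders
  (an artifact of `seq()` accumulation) and clamps instead of invalidating.
- Frames whose resampled intensities stray within 1e-6 outside
  [0, max_level] are clamped, not rejected.
- Spatially constant image statistics yield an empty overlay mask with a
  warning; masks covering 50% or more of the frame are refused outright.
- Fewer than 3 centroids: curvature is reported absent (`NA`), not zero.
- Volumes without intensity contrast raise a "no detectable surface" error
  in the step metric rather than returning a meaningless roughness.
- Problem sizes used by the shipped verification runs: the ring analysis
  rasterizes the default phantom at 0.05 mm voxels over 25 x 25 x 15 mm and
  reconstructs 275 slices at 1 mm/s; registration recovery uses 2 s sweeps
  over a uniform speckle phantom at 0.1 mm pixels; the speed-ordering runs
  use a 16 mm dome sweep at 0.1 mm voxels. These sizes were chosen so each
  property is measured well clear of its discretization floor.

## Known limitations

- Translation-only registration cannot represent rotation about the probe
  axis; a visibly rotating capture should be excluded upstream.
- Sequential registration cannot distinguish probe drift from genuine
  structural change along the sweep: where a single bright surface
  dominates the frame and its depth varies with elevation (an isolated
  dome, a steep scleral wall), the correlation tracks the surface and the
  accumulated "drift" bends the reconstruction. On sweeps anchored by
  stationary full-frame content (a globe cross-section, the uniform
  speckle of a gelatin phantom) cumulative recovery is within a few
  percent. For isolated-structure phantom sweeps without appreciable
  drift, disable registration or bound `max_shift` tightly; the per-frame
  score and drift table in the output make the failure mode visible.
- The single-sweep scope matches the acquisition protocol (one horizontal
  sweep per scan); compounding multiple sweeps is future work.
- Sector parameters must come from the vendor or be calibrated; the
  identity fallback leaves fan distortion uncorrected for probes without
  them, exactly as raw vendor display does.
- MP4/AVI containers are not decoded in-process; captures are ingested as
  PNG sequences with a JSON sidecar (the same intermediate the original
  processing chain used), and a video reader can be plugged in behind
  `extract_frames()`.
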