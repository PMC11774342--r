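# bscan3d

3D reconstruction of linearly swept 2D ophthalmic B-scan ultrasound.

A conventional B-scan probe produces 2D cross-sections of the eye. Mounted
on a linear actuator and translated at constant speed `v` across the closed
eyelid (or a test phantom), its screen-captured video becomes an implicit 3D
dataset: frame `i`, acquired at time `t_i`, is a slice at elevation
`y_i = v · t_i`. **bscan3d** turns such a capture into an explicit,
geometrically corrected volume, for anyone building or validating low-cost
3D ocular ultrasound: it

- collapses duplicated container frames (screen capture repeats each B-scan
  until the probe refreshes; a 30 fps recording of an 11 fps probe carries
  every frame ~3×),
- removes burnt-in annotations, detected as high-intensity pixels that stay
  constant through the time series while echo speckle decorrelates,
- corrects in-plane probe drift by translation-only normalized
  cross-correlation between sequential frames, with log-parabola subpixel
  refinement,
- undoes sector-scan distortion (`x = r sin θ`, `z = r cos θ − apex`) by
  resampling fan-geometry frames onto a Cartesian grid — the correction that
  makes a physically flat grid stop looking curved,
- stacks the slices by linear interpolation along the elevation axis and
  writes a NIfTI-1 volume whose affine carries voxel spacing and world
  origin, plus a validity-mask companion and a JSON provenance sidecar.

A phantom/sweep simulator (`rasterize_phantom()`, `simulate_sweep()`)
generates ground-truth test objects — a planar bar grid, a wax-style dome,
and a resin-style dome bearing 6 concentric 0.3 mm rings — with Gaussian
point spread, elevation-correlated Rayleigh speckle, injected drift and
overlays, so the entire chain is testable without clinical data.
Quantitative QC metrics (`noise_stats()`, `curvature_and_angulation()`,
`ring_profile_metrics()`, `step_artifact_metric()`) make the usual visual
judgments — ring resolvability, flat-grid curvature, staircase artifacts at
fast sweep speeds — reproducible numbers.

## Worked example

Reconstruct a simulated screen-captured sweep of the 6-ring resin-style
phantom with the A12 preset (11 fps native content inside a 30 fps
container, speckle, crosshair overlay):

```r
library(bscan3d)

phantom <- phantom_spec("spherical_grid")      # 6 rings, 0.3 mm wide
truth   <- rasterize_phantom(phantom, voxel_size = 0.1,
                             extent = c(25, 25, 12))
probe   <- probe_preset("A12")
sweep   <- sweep_spec(speed = 1, duration = 25)   # 1 mm/s sweep

sim   <- simulate_sweep(truth, sweep_sim_config(
  probe, sweep, container_rate = 30, speckle_contrast = 0.3,
  speckle_seed = 1, overlay = "crosshair"))
recon <- reconstruct_sweep(sim$sequence, probe, sweep, register = FALSE)
summary(recon)
#> <bscan3d_recon> 750 input frames -> 272 slices -> 251 x 250 x 121 volume
#>   effective rate 10.869 fps, elevation extent 24.933 mm
#>   voxel spacing: 0.1 x 0.1 x 0.1 mm
#>   overlay coverage: 2.437%

ring_profile_metrics(recon$volume)
#> <ring_report> 6 rings detected, median width 0.356 mm

write_reconstruction(recon, "phantom.nii.gz")
```

750 recorded frames reduce to 272 distinct B-scans; the crosshair (2.4% of
each frame) is detected and inpainted; all 6 rings are resolved at close to
their physical 0.3 mm width. Registration is off here because an isolated
dome is the only structure in the frame and sequential correlation would
track its changing cross-section as apparent drift (see the methods
vignette); on sweeps with stationary anchoring content it recovers drift
precisely:

```r
gel <- us_volume(array(0.5, c(121, 81, 81)), rep(0.1, 3))  # speckle phantom
sim <- simulate_sweep(gel, sweep_sim_config(
  probe, sweep_spec(1, 2), 30, speckle_contrast = 0.8, speckle_seed = 1,
  drift_per_frame = c(0.5, -0.25), y_start = 3))
est <- estimate_drift(deduplicate_frames(sim$sequence))
tail(est$table, 1)      # injected cumulative drift: (+10.5, -5.25) px
#>    frame        dx       dy     score
#> 22    22 -10.55899 5.258384 0.9507772
```

The estimated correction (−10.56, +5.26) undoes the injected (+10.5, −5.25)
drift to within 0.6%.

A thin command-line front end (`inst/cli/bscan3d`) exposes `reconstruct`,
`simulate` and `qc` subcommands over the same functions.

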