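Package: bscan3d
Title: 3D Reconstruction of Linearly Swept Ophthalmic B-Scan Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts an ordered sequence of 2D B-scan ultrasound frames,
    captured while a probe is translated at constant speed across the eye
    or a test phantom, into a registered, annotation-free, geometrically
    corrected 3D volume stored as NIfTI. Provides frame extraction and
    deduplication for screen-captured probe video, translation-only drift
    registration by normalized cross-correlation, removal of static
    on-screen overlays detected as bright temporally constant pixels,
    sector-to-Cartesian scan conversion, elevation-axis linear
    interpolation onto a regular voxel grid, a parametric phantom and
    sweep simulator with speckle and point-spread blur, and quantitative
    quality metrics (noise statistics, grid curvature and angulation,
    concentric-ring resolvability, scan-speed step artifacts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    png,
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
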