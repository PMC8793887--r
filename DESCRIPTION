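Package: VoxelFlow
Title: Voxel-by-Voxel 4D-Flow MRI Hemodynamic Mapping of the Thoracic Aorta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies thoracic aortic hemodynamics from time-resolved
    three-directional phase-contrast (4D-flow) MRI velocity fields on a
    voxel-by-voxel basis. Provides preprocessing (noise masking, temporal
    velocity anti-aliasing, eddy-current background-phase correction,
    PC-MRA derivation), centerline extraction with nearest-plane voxel
    matching, parametric maps of forward and reverse flow, flow stasis,
    kinetic energy and systolic peak velocity, five-region aortic
    summaries with BSA-indexed diameters and dilation grading, Reynolds
    number at the vena contracta, and a cohort statistics stage
    (normality-gated group tests, effect-size-gated correlations,
    standardized multivariable regression). Includes a ground-truthed
    pulsatile tube-flow phantom generator (straight and aorta-like
    candy-cane geometries) with configurable retrograde and helical flow,
    venc phase wrapping, noise and eddy-current-like offsets, plus a
    synthetic cohort simulator for calibrating the statistics stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
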