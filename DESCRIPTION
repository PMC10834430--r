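Package: bonessm
Title: Statistical Shape Modelling for Bone Segmentation Refinement and
    Cartilage Finite-Element Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building statistical shape models (SSM) of bone
    surfaces from corresponded point sets, adjusting coarse binary
    segmentations into smooth surfaces suitable for finite-element meshing,
    and preparing cartilage volume meshes.  Includes mesh and voxel-mask
    data structures with PLY/STL/OFF/VTK and NIfTI input/output, surface
    extraction from binary masks, Taubin smoothing, Poisson-disk surface
    sampling with uniformization, coarse principal-axes alignment, coherent
    point drift (rigid and non-rigid) registration, generalized Procrustes
    analysis, thin-plate-spline warping, segmentation-quality metrics (Dice,
    Hausdorff, average surface distance, area fraction beyond a distance
    threshold), layered hexahedral cartilage extrusion with Abaqus INP
    export, and one-dimensional statistical parametric mapping with
    random-field-theory thresholds for comparing stance-phase trajectories.
    A synthetic-data module generates bone-like shape populations, degraded
    segmentation masks, cartilage surfaces and trajectory ensembles for
    fully reproducible end-to-end runs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
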