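Package: capfuse
Title: MRI-CT Fusion Imaging and Surgical Simulation for Capitellar
    Osteochondritis Dissecans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds three-dimensional MRI-CT fusion images (MCFIs) of the
    humeral capitellum for preoperative evaluation of osteochondritis
    dissecans (OCD). Provides threshold segmentation of bone and cartilage
    with detectors for articular cartilage fissures (ACF), cartilage
    defects (ACD), surface deformities (ASD), segmented subchondral bone
    (SSB) and subchondral sclerosis; iso-surface mesh reconstruction;
    landmark (N-point) rigid registration refined by iterative closest
    point; quadrant-based lesion localization, diameter measurement, a
    codified stability rule and ICRS class prediction; geometric surgical
    simulation of lesion resection, costal and cylindrical osteochondral
    graft placement and drilling trajectories; and concordance statistics
    (corresponding rates, medians, Mann-Whitney tests) over packaged
    per-case outcome tables. A synthetic capitellum phantom with full
    geometric ground truth makes every stage testable without clinical
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
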