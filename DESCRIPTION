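Package: podsplit3d
Title: Multimodal Segmentation of Touching Pod-Shaped Objects from
    Structured-Light Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates physically touching (adherent) pod-shaped objects such
    as peanut pods in top-down images with the help of a line-structured-light
    3D scan. Provides laser-stripe centerline extraction and light-plane
    triangulation to build a spliced world-frame point cloud, PCA surface
    normals and surface-variation curvature, curvature-seeded region growing
    to split the cloud into individual pods, rolling-ball (alpha-hull) 2D
    boundary extraction per pod, shape-based template matching with
    least-squares sub-pixel pose refinement to map each pod back onto the 2D
    image, pixel-accuracy and mean-success-rate evaluation metrics, and a
    ground-truthed synthetic scene generator (five pod morphologies, simulated
    stripe stacks, rendered top-down scenes) replacing the capture rig.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    tools,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
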