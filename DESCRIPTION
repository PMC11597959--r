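Package: pluckvision
Title: RGB-D Vision Geometry for Robotic Flower Harvesting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometry pipeline for selective robotic harvesting of edible
    flowers from RGB-D frames. Given a color image, an organized point cloud
    aligned with it, and per-flower detections and segmentation masks from a
    pluggable upstream detector, the package cleans the masks, isolates each
    flower's 3D points, estimates its pose by principal component analysis,
    measures its diameter from the convex hull of the flower-plane
    projection, locates its center at the Chebyshev center of the mask
    polygon, predicts the cut depth from a per-species linear calibration
    with an 85 percent upper-boundary line, and translates the flower center
    along the main pose axis to the 3D plucking point. Includes file-based
    adapters for external deep detectors, a classical color-blob fallback
    detector, a synthetic RGB-D scene generator with ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    EBImage,
    pracma
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'detect-adapter.R'
    'mask-ops.R'
    'morphometry.R'
    'pipeline.R'
    'pluckvision-package.R'
    'ply-io.R'
    'pose3d.R'
    'scene-io.R'
    'synthetic.R'
    'utils.R'
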