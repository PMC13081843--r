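Package: deciduamap
Title: 3D Spatial Quantification of Trophoblast Invasion and Spiral Artery
    Remodeling at the Implantation Site
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the mouse maternal-fetal interface from 3D
    point detections exported by image-segmentation software. Fits an
    anatomical half-dome coordinate frame from labelled landmarks, maps
    trophoblast and artery detections onto a normalized placenta-to-myometrium
    depth axis, estimates 3D kernel densities and their Bhattacharyya overlap
    with bootstrap confidence intervals, classifies trophoblast localization
    (interstitial, spiral-artery-adjacent, myometrial), computes artery
    branch, envelopment and placental-connection metrics from centerline
    trees, compares virtual 2D sections against full 3D measurements, and
    provides the group-comparison statistics and delta-delta-Ct calculations
    used for decidualization readouts. Includes a synthetic implantation-site
    generator with control and knockout-like presets so every stage of the
    pipeline can be exercised and validated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
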