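Package: angiotrack
Title: Vessel Analytics for Coronary X-Ray Angiography Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-segmentation analytics for coronary X-ray angiography
    sequences. Starting from per-frame binary vessel masks, the package
    extracts single-pixel centerlines by Zhang-Suen thinning with staircase
    smoothing, detects skeleton endpoints and bifurcations, splits the
    skeleton into vessel segments and measures per-segment diameter profiles
    along centerline normals, assembles a ternary vessel tree rooted at the
    catheter-proximal segment, matches vessels across frames by start/end
    position and length, quantifies and grades diameter stenosis, and flags
    myocardial bridges from periodic narrowing along a vessel track. A
    seeded synthetic phantom generator produces mask sequences with
    ground-truth sidecars for validation, and evaluation utilities (Dice,
    average symmetric surface distance, accuracy/recall) compare
    segmentations against references.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
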