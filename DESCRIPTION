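Package: rblmeasure
Title: Radiographic Bone Loss Measurement from Tooth Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit that turns per-tooth segmentation masks of
    dental panoramic radiographs into radiographic bone loss (RBL) percentages
    and periodontitis bone-loss stages. Given a four-class region label map
    (background, intrabony root, suprabony root, crown) and a stack of
    overlapping per-tooth position masks in the universal numbering system, it
    extracts the dental region, merges positions with regions into per-tooth
    masks, estimates each tooth's long axis by principal component analysis of
    pixel coordinates, clips that axis against the convex hulls of the
    suprabony and whole-root regions, and reports RBL% = 100 * A / B together
    with stage assignments (I < 15%, II in [15, 33), III >= 33%). Also includes
    landmark-based reference measurements (CEJ-ABC-AP ratios), framework-free
    reference implementations of per-pixel multi-label and cross-entropy
    losses and the standard segmentation metrics (IoU, F1, pixel accuracy,
    sensitivity, specificity), report builders, and a seeded synthetic tooth
    phantom generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    png,
    ggplot2,
    generics,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
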