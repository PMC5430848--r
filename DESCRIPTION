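Package: cocultrack
Title: Cell Tracking and Motility Analysis for Microfluidic Immune-Tumor
    Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised single-particle tracking pipeline for time-lapse
    fluorescence recordings of immune cells migrating toward tumor cells in
    two-sided microfluidic co-culture devices. Provides a parametric model of
    the device geometry (central immune chamber, arrays of narrow connecting
    channels, collagen tumor chambers), layout-driven background elimination,
    per-frame cell segmentation, frame-to-frame trajectory linking with gating
    and gap closing, compartment-aware motility metrics (migrating and
    infiltrating cell counts, pre- and post-channel speed, displacement,
    directional persistence), dwell-time analysis of immune-tumor cell
    interactions within a circular contact region, and a synthetic time-lapse
    generator (confined biased persistent random walks rendered as noisy
    fluorescence movies) so that every stage of the pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    EBImage,
    rlang,
    stats,
    tibble,
    tiff,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
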