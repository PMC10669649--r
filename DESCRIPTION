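Package: necrovol
Title: Quantification of Ablation Zones in Serial Histological Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Semi-automated quantification of necrotic ablation zones in
    serial histological sections of NADH-diaphorase stained tissue.
    Provides color-based segmentation of viable versus necrotic tissue,
    per-slice area measurement, depth and volume estimation from the
    anisotropic sectioning geometry (section thickness plus inter-section
    spacing), hemi-section (top-half) quantification, rigid serial-section
    registration, voxel and surface-mesh 3D reconstruction, and two-sample
    group comparison. A synthetic phantom generator with exact ground
    truth makes every stage testable without real histology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
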