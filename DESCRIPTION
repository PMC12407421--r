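Package: morphadapt
Title: Synthetic Multiview Specimen Imagery and Domain-Adaptive
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for studying sim-to-real domain
    adaptation in specimen image classification. Provides a procedural
    specimen forge (parameterised skull-like triangle meshes with
    within-species variation), mesh standardisation and Wavefront OBJ
    input/output, a self-contained software rasterizer that renders each
    specimen from a view-sphere camera lattice, a simulated photograph
    domain with turntable-like background markings and photometric
    nuisance shifts, specimen-level data splitting and augmentation, a
    small convolutional classifier trained under six regimes including a
    maximum mean discrepancy (MMD) feature-alignment objective,
    fine-tuning and supplementation, and an evaluation suite with
    confusion matrices, t-SNE silhouette domain-confusion analysis and
    Grad-CAM focus scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
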