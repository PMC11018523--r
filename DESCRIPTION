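Package: rootseg
Title: Transformer Segmentation and Senescence Analysis of In Situ Root Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for semantic segmentation and senescence analysis of
    high-resolution in situ root scans (minirhizotron / rhizobox imagery).
    Implements a hierarchical mix-transformer encoder with efficient
    (sequence-reduced) self-attention and Mix-FFN blocks, a family of
    lightweight decoders (UNet-style skip fusion, depthwise-separable,
    all-MLP, transposed-convolution, sub-pixel and ASPP variants), a
    CPU training harness (AdamW, cosine annealing, paired augmentation),
    confusion-matrix segmentation metrics, tiling of giant scans with
    exact stitching, four-class senescence post-processing with SLIC
    superpixel majority correction, time-series pixel statistics with
    cubic trajectory fitting, a classical (non-learning) senescent-root
    extraction baseline, and a deterministic synthetic root-scene
    generator with paired ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jpeg,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
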