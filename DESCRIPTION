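Package: brainseg
Title: Fuzzy Local-Information Segmentation and Swarm-Optimized Feature
    Selection for Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for brain-tumor MRI analysis on 2-D slices: ground-truthed
    phantom simulation (multi-tissue slices with skull ring, bias field and
    Rician noise), preprocessing (skull stripping, median filtering and
    entropy-adaptive contrast-limited histogram equalization), intuitionistic
    fuzzy c-means clustering with a local spatial-information penalty
    (LWIFCM), a chameleon swarm optimizer that searches the clustering's
    initial centers and key parameters, binary chaotic transient-search
    wrapper feature selection over cross-validated classifier accuracy, a
    layer-shape calculus with seeded random-weight forward passes for a
    channel-expansion residual attention network, and segmentation /
    classification evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    class,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
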