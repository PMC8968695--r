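Package: nephroseg
Title: Coarse-to-Fine Kidney Tumor Segmentation with Attention-Gated
    Recurrent-Residual U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage (coarse-to-fine) pipeline for segmenting kidneys
    and kidney tumors in axial CT slices. Provides fuzzy-set gray-level
    enhancement, an attention-gated U-shaped network whose encoder and
    decoder use recurrent-residual parallel-convolution blocks with
    Leaky-ReLU activations, region-of-interest extraction with the
    128/256 window-expansion rule, tumor-size dataset balancing by
    geometric augmentation, smoothed Dice evaluation, and a deterministic
    synthetic-phantom generator so the whole cascade can be trained and
    tested at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
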