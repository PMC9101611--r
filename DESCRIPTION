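Package: lesiontex
Title: Texture Analysis of Pigmented-Lesion Dermoscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the texture of dermoscopy regions of interest (ROIs)
    from pigmented skin lesions. Implements co-occurrence-matrix entropy and
    difference entropy, run-length-matrix long-run emphasis, and the derived
    texture index (TI) and bone index (BI), after mean +/- 3 SD intensity
    windowing and gray-level quantization. Includes a normality-routed
    three-group comparison stage (Shapiro-Wilk gate, one-way ANOVA with Tukey
    HSD or Kruskal-Wallis with Dunn-Bonferroni post hocs), a calibrated
    synthetic generator of lesion-like textures in three classes (benign
    nevus, dysplastic nevus, melanoma) under polarized and non-polarized
    light, and an end-to-end pipeline producing per-ROI feature tables and
    group-comparison reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
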