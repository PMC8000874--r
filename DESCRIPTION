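Package: impactT2
Title: Quantitative T2 Mapping and GLCM Texture Analysis of Impacted
    Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal multi-echo spin-echo MRI of articular
    cartilage explants exposed to drop-tower impaction, fits pixel-wise
    mono-exponential T2 maps, partitions sample masks into equally thick
    superficial and deep layers, extracts gray-level co-occurrence matrix
    (GLCM) texture features (contrast, homogeneity, energy, variance) with
    four-orientation averaging, and runs the longitudinal nonparametric
    statistical battery (Friedman with Dunn post hoc, Kruskal-Wallis,
    one-way ANOVA with Tukey post hoc on relative changes) used to
    characterise post-traumatic cartilage degeneration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
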