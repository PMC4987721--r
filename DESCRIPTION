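Package: fadyn
Title: Quantitative Analysis of Focal Adhesion Dynamics, Cell Migration
    and Micropillar Traction Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-content imaging studies of focal adhesion (FA)
    dynamics. Segments nuclei and focal adhesions from fluorescence images
    and extracts per-adhesion morphometric features; calls siRNA-screen hits
    from shifts in adhesion-size distributions with a signed two-sample
    Kolmogorov-Smirnov test evaluated in the log10 p-value domain; tracks
    migrating cells by frame-to-frame mask overlap and compares single-cell
    speed populations with Kruskal-Wallis and Dunn's post test; and converts
    micropillar-array movies into per-pillar traction forces via sub-pixel
    localization against a fitted reference hexagonal grid, including force
    autocorrelation half-times and nested-model comparisons. Seeded synthetic
    image and movie generators with full ground truth support validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
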