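Package: tfscreen
Title: Metrology and Classification for a Transition-Fibre Protein Screen
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative pipeline for a fluorescence-microscopy screen of
    transition-fibre proteins at the flagellar base. Renders synthetic
    dual-channel scenes with known geometry (Gaussian PSF, Poisson and read
    noise), localises puncta to sub-pixel precision by 1D Gaussian fitting,
    measures distance to the nearest basal-body marker focus and the
    45-line angular "pseudo-diameter" of appendage structures, applies the
    screen's inclusion gate against control baselines, classifies
    recruitment timing and new/old-flagellum intensity bias, computes
    flagellum-length morphometrics and rank-based group comparisons, and
    resolves reciprocal-best-hit orthology over precomputed alignment hit
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
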