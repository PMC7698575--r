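Package: yellowpix
Title: Quantification of Yellow Skin Pigmentation from Fish Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated, non-invasive quantification of yellow skin
    pigmentation in fish from standardized digital photographs. Counts
    foreground pixels falling inside an inclusive RGB colour box, measures
    their spatial dispersion with the standard distance deviation (SDD),
    builds magenta-overlay diagnostics and per-treatment mean images, and
    tests dietary effects with rank-based permutation statistics (one-way
    and two-way crossed ANOSIM with Bonferroni pairwise post-hocs, Mantel
    matrix correlation) plus one-way ANOVA with Tukey compact letter
    displays for growth traits. Includes a fully seeded synthetic
    fish-image study generator with ground truth, so the entire pipeline
    is testable end to end without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
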