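Package: stemcycle
Title: Pseudotime Expression Trends and Cell-Cycle Kinetics for Stem and
    Progenitor Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for studying proliferation of neural stem and
    progenitor cell populations from single-cell expression data and
    cumulative S-phase labeling experiments. Implements relative-expression
    trend fitting along a pseudotime trajectory with a stationary-point stage
    cutoff, Tirosh-style summed-marker cell-cycle scoring with median
    normalization and cycling/positivity association, two-segment (rise plus
    plateau) regression of cumulative EdU/BrdU labeling timecourses yielding
    growth fraction and cell-cycle and S-phase lengths, stereological count
    scaling, Fisher's exact association on 2x2 tables, and seeded synthetic
    data generators with the statistical structure each stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
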