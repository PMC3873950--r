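Package: rootarch
Title: Deep Phenotyping of 3D Coarse Root System Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for architectural analysis of 3D-digitized coarse root
    systems of container-grown seedlings. Parses a documented dialect of the
    multitree graph (MTG) text format and a portable segment table, computes
    a full battery of architectural traits (axis geometry, 10 mm virtual
    segmentation, wall-artifact correction, eight-compartment classification,
    slope-oriented circular sectors, topological index qb, mean branching
    order, fractal branching parameters), simulates container-grown seedling
    root systems with controlled architecture, and runs the statistical layer
    used in root phenotyping studies: three-way ANOVA with block, sector
    mixed models with contrasts, and PCA of trait tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    lmerTest,
    emmeans,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
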