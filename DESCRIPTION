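Package: inputmap
Title: Brain-Wide Rabies Virus Input Mapping Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for brain-wide rabies-virus (RABV) monosynaptic
    input tracing to midbrain dopamine neurons. Provides a canonical 22-region
    input vocabulary with Allen-atlas mappings, count-table I/O and quality
    filtering, percentage and Z-score normalization, PCA with loading
    interpretation and condition statistics, ensemble nonlinear-embedding
    correlograms with a scramble permutation null, starter-cell
    center-of-mass confound regressions, projection-portrait construction
    from connectivity-atlas density grids, and correlation of
    condition-induced labeling changes with regional gene-expression atlases
    (Spearman screens, hypergeometric gene-set enrichment, gene-class
    regressions). A synthetic-data generator with planted effects provides a
    ground-truth test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    cluster,
    multcomp,
    uwot,
    FNN,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
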