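Package: scaffoldspace
Title: Scaffold-Ordered Chemical Space Embedding on Pseudo-Hilbert Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic, medicinal-chemistry-interpretable two-dimensional
    embedding of compound libraries. A reference chemical space is defined by a
    set of Bemis-Murcko scaffolds ordered by a 32-key scaffold descriptor
    vector ("scaffold keys"); the ordered scaffolds are folded onto a
    pseudo-Hilbert curve of chosen order, and compounds are placed at the grid
    cell of their nearest reference scaffold under the scaffold-key distance.
    Includes rank and Chebyshev distance measures in the embedded space, a
    count-vector overlap statistic for comparing embeddings, coverage heatmaps,
    distance-correlation diagnostics, and deterministic synthetic fixture
    generators. Standard cheminformatics operations (SMILES parsing,
    standardization, scaffold extraction, InChI-Keys, Morgan fingerprints) are
    delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, discoverable as 'python' on
    the PATH (override with option 'scaffoldspace.python').
Config/testthat/edition: 3
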