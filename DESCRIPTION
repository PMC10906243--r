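Package: pepcatml
Title: Machine-Learning-Guided Optimization of Tripeptide Catalysts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for data-driven discovery of stereoselective
    tripeptide catalysts. Enumerates combinatorial Pro-Pro-Xaa-type
    in-silico libraries from amino-acid building blocks, computes
    conformer-averaged steric (ASO) and electronic (AEIF) grid
    descriptors over aligned conformer ensembles, designs compact
    Universal Training Sets by k-means clustering of descriptor space,
    models enantio- and diastereoselectivity on a free-energy scale
    with latent-structure (PLS) regression, and runs iterative,
    uncertainty-aware optimization campaigns over the full library.
    Includes a synthetic-data generator so every stage is testable
    without external downloads.
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
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    kernlab,
    ranger,
    nnet,
    withr,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
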