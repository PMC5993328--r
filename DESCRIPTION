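Package: envdms
Title: Environment-Resolved Deep Mutational Scanning Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for environment-resolved deep mutational
    scanning (DMS) of a single gene: variant calling from amplicon reads with
    quality and count filters, depth-normalized log2 preferential-enrichment
    fitness scores, environment-level selection statistics (viability
    selection coefficients with conjugate Bayesian posteriors, delta-F,
    mutational robustness rho, positive/negative effect ratios with
    replicate-noise thresholds), biophysical-constraint analysis
    (feature-fitness correlation matrices, folding-by-binding mutant subsets,
    subset-wise selection, bootstrap cross-environment correlations), and
    folding-by-binding fitness-landscape grids via nearest-neighbor
    interpolation. Includes a fully specified synthetic-data generator
    (library, biophysical ground truth, multinomial sampling, FASTQ emission)
    so the whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    methods
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
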