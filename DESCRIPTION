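Package: tumoreqtl
Title: Cell-Type-Aware cis-eQTL Mapping from Bulk Tumor Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps expression quantitative trait loci (eQTLs) that can be
    confidently attributed to cancer cells using bulk tumor expression data
    and per-sample tumor-purity estimates. Implements the conventional
    bulk-tissue eQTL regression, a purity-by-genotype interaction model whose
    genotype main effect extrapolates the eQTL effect to 100% cancer cells, a
    Z-test for effect-size differences between cohorts, and a simulation
    framework that mixes latent cancer and normal expression compartments
    with known eQTL architecture to benchmark sensitivity, specificity and
    realized false-discovery rates. Includes preprocessing utilities
    (quantile and inverse-normal transforms, expression and allele-frequency
    filters, cis-window pairing, genotype and expression principal
    components, Lasso-based purity transfer between cohorts), evaluation
    tools including a purity-measurement noise sweep, TSV/VCF readers and
    writers, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
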