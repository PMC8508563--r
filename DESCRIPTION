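Package: msimeth
Title: Interaction of Microsatellite Instability and Tumor DNA Methylation
    in Paired Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide analysis of how microsatellite instability (MSI)
    modifies tumor-versus-normal DNA methylation differences in paired
    colorectal cancer designs. Provides per-CpG paired and interaction
    ANOVA models with a random subject effect and method-of-moments
    variance components, variance decomposition, FDR plus magnitude
    calling of differentially methylated loci, interaction-category
    classification, CpG island/shore/shelf region tabulation, chi-square
    gene-category enrichment scoring, cohort characteristic tests, and
    paired expression fold-change analysis, together with a synthetic
    data generator emulating the paired study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
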