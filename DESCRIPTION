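Package: ithlayers
Title: Multi-Region Multi-Omic Intratumor Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intratumor heterogeneity (ITH) from multi-region
    tumor sequencing across four molecular layers. Applies somatic-call
    quality control, filtering and cross-region rescue, trunk/branch
    mutation classification, tumor mutation burden, arm-level copy-number
    calls, tumor-purity correction of methylation and expression profiles,
    Jaccard-distance and Jensen-Shannon-distance ITH metrics,
    minimum-evolution phylogenetic and phyloepigenetic trees rooted at the
    matched normal, cross-layer correlations, and median-split survival
    stratification. Includes a synthetic multi-region cohort generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
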