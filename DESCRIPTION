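Package: coregen
Title: Identification and Principal Network Projection of Genetic-and-Epigenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic-and-epigenetic networks (GENs) from cohort
    expression data and database-derived candidate edges. Bilinear
    protein-association and linear TF/miRNA gene-regulatory models are fitted
    per target by least squares; model order is detected by AIC over a
    backward-elimination path and insignificant regulatory abilities are
    pruned by Student's t-test. The identified ability matrices are stacked
    into a network matrix whose singular value decomposition (Principal
    Network Projection) scores every protein, transcription factor and miRNA
    by its projection distance onto the top principal components; thresholding
    these distances extracts core networks, and differencing two cohorts'
    cores yields common and cohort-specific core networks together with
    DNA-methylation (basal-level shift) and differential-expression candidate
    annotations. A seeded synthetic-data module forward-simulates cohorts from
    known ground-truth networks so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
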