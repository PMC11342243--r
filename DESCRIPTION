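Package: mddsig
Title: Imaging-Transcriptomics Gene Signatures in Major Depressive Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene signatures of major depressive disorder by
    correlating spatial gene expression profiles with case-control brain
    imaging contrast maps (ALFF, fALFF, ReHo and grey matter density) under
    a permutation null, and classifies genes by directional effect.
    Characterizes the resulting classes by protein-interaction network
    topology, temporal-spatial expression specificity on developmental
    transcriptomes via the specificity index (SPI) and dispersion index
    (DPI), reference-list overlap and hypergeometric term enrichment, and
    sex-differential expression. Ships a synthetic-data generator with
    planted ground truth so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
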