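Package: c4coex
Title: Comparative Leaf-Gradient Co-Expression Networks for C4 Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative transcriptome analysis of leaf developmental gradients
    across C3 and C4 grasses. Builds per-species weighted gene co-expression
    networks (soft-thresholded Pearson adjacency, topological overlap, dynamic
    branch cutting, eigengene merging), compares modules across species through
    syntenic orthologues (Fisher overlap, functional-bin enrichment), detects
    sign-separated differential co-expression modules between a C4 species and
    the C3 reference, and classifies C4 candidate genes into level-shifted
    (type I), pattern-changed (type II) and orthologue-absent (type III)
    classes. Ships a synthetic leaf-gradient data generator with planted ground
    truth for end-to-end validation, plus a single-config pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust,
    jsonlite
Config/testthat/edition: 3
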