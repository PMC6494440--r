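Package: netkda
Title: Key-Driver Validation of Gene Signatures in Causal Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow that validates a candidate network key
    driver against genotype-structured transcriptome data. Starting from a
    gene-by-sample count matrix over a six-genotype mouse design (wild type,
    driver heterozygous/knockout, amyloid model, and their crosses), the
    package filters and TMM-normalizes counts, fits empirical-Bayes moderated
    linear models per contrast, calls directional differential-expression
    signatures, tests direction-aware signature overlaps by Fisher's exact
    test with fold enrichment, layers the downstream neighborhood of a seed
    gene in (unions of) directed causal networks by breadth-first distance,
    scores per-layer signature enrichment, ranks genome-wide key-driver
    candidates, and detects co-expression modules for module-signature
    enrichment. Negative-binomial count, planted-driver network, and
    latent-factor co-expression simulators provide ground truth for
    end-to-end parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
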