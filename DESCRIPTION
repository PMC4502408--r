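Package: repde
Title: Reproducibility-Based Differential Expression for Technical-Replicate Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed genes between two clonal cell-line
    phenotypes (e.g. drug-resistant vs drug-sensitive) measured with only two or
    three technical replicates each, where variance-based statistics are
    uninformative. Genes are ranked per resistant-sensitive sample pair by the
    pairwise difference (PD) or pairwise fold change (PFC) of linear-scale
    intensities; reproducibility of dysregulation directions between independent
    sample pairs is scored with an exact cumulative binomial test; reproducible
    sample pairs are selected and a block-wise consistency search with step
    halving extracts the reproducible DE genes. Includes hypergeometric gene-set
    over-representation with Benjamini-Hochberg control, a synthetic
    technical-replicate data generator with intensity-dependent noise, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
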