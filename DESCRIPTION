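Package: genetopics
Title: Interpretation of Gene Sets via Literature-Driven Topic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates an input gene set by mining the biomedical literature
    attached to it. The package assembles a corpus of titles and abstracts
    for the input genes together with an equal-sized random background gene
    set, fits a latent Dirichlet allocation topic model by collapsed Gibbs
    sampling, scores every gene against every topic by the maximum
    document-topic proportion over the gene's documents, and selects topics
    specific to the input genes with a one-tailed binomial test against the
    embedded random genes, with Bonferroni correction. It reports, per
    selected topic, the top terms, the member genes with their scores and
    the supporting document identifiers, and ships a synthetic corpus
    generator with known planted topic structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
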