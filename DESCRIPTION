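Package: cidrex
Title: Chemical-Induced Disease Relation Extraction from Annotated Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A mention-pair relation extraction system for chemical-induced
    disease (CID) relations in PubMed titles and abstracts.  Parses the
    PubTator exchange format, constructs intra- and inter-sentence
    chemical/disease mention-pair instances with heuristic distance and
    parenthesis filters, removes hypernym-redundant training negatives and
    predictions using MeSH tree numbers, extracts sparse lexical and
    dependency-path string features, classifies instances with
    maximum-entropy (L2-penalized logistic) models, merges mention-level
    decisions into document-level relations, and evaluates predictions with
    precision, recall and F-score.  Includes a seedable synthetic corpus
    generator with planted relations and hypernym structure for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
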