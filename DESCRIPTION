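Package: provpath
Title: End-to-End Provenance Representation for Scientific Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for describing the complete path of a scientific
    experiment -- its computational and non-computational steps, data,
    agents, instruments, settings and materials -- as linked provenance
    under the REPRODUCE-ME extension of the W3C PROV-O and P-Plan
    ontologies. Provides a typed experiment model with a
    reproducibility/repeatability change classifier, an ontology term
    registry and emitter, RDF graph construction and Turtle/RDF-XML/N3
    serialization, prospective and retrospective provenance extraction for
    computational notebooks (nbformat v4) and script runs, structural
    validation of provenance graphs, competency-question queries, and a
    seeded synthetic-experiment generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
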