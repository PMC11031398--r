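Package: neurotraj
Title: Clinical Disease Trajectories for Neurodegenerative Brain Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to convert year-anchored clinical-history text into per-donor
    sign/symptom disease trajectories and to analyse them across
    neuropathologically defined brain disorders. Includes an ontology data
    model for 90 neuropsychiatric signs and symptoms, sentence/year parsing,
    multilabel bag-of-words and linear-SVM sentence classifiers with
    multilabel-stratified cross-validation, persistence imputation and cohort
    filters, permutation-test enrichment with Benjamini-Hochberg correction,
    temporal and survival profiling, clinical-versus-neuropathological
    diagnosis concordance, trajectory-based diagnosis prediction, and
    two-modality weighted-nearest-neighbor clustering for data-driven clinical
    subtypes. A synthetic-cohort generator with planted statistical structure
    stands in for restricted brain-bank donor records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    e1071,
    igraph,
    survival,
    nnet,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
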