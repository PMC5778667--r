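Package: chemosig
Title: Chemotherapy Mutational Signatures and Neoantigen Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the contribution of chemotherapy to somatic
    mutation and predicted-neoantigen burden in tumor cohorts. Extracts
    treatment-associated mutational signatures from treated/control preclinical
    replicate experiments with a Poisson background/treatment model, adjusts
    them for genome trinucleotide composition, deconvolves per-sample signature
    mixtures against a reference catalogue by iterated nonnegative least
    squares with a detection threshold, attributes individual mutations (and
    their neoantigen yields) to signatures by posterior probability, and runs
    patient-reweighted, tissue-stratified burden comparisons with bootstrap
    confidence intervals. Includes a synthetic cohort generator with known
    ground truth so every stage of the pipeline is testable without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
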