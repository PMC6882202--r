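Package: recurneo
Title: Identification and Ranking of Recurrent Neo-Epitopes from Somatic
    Variant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and prioritize recurrent tumor neo-epitope
    candidates from cohort-level somatic variant tables. Reads MAF-dialect
    mutation tables, applies high-confidence missense SNV filters, calls
    per-cohort recurrent amino-acid exchanges, enumerates 9-11-mer peptide
    windows around each exchange, scores them through a pluggable MHC class I
    binding predictor, ranks candidates by the expected number of newly
    diagnosed patients carrying both the mutation and a binding HLA allele,
    quantifies robustness of patient coverage to false-positive candidates by
    resampling, and screens calls for homopolymer-context sequencing
    artifacts. Includes a synthetic cohort generator with ground-truth labels
    so the entire pipeline can be exercised without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
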