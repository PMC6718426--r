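Package: mocprog
Title: Genomic Progression Analysis of Mucinous Ovarian Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the genomics of mucinous ovarian tumor
    progression (benign cystadenoma, borderline tumor, and grade 1-3
    carcinoma). Implements a multi-caller somatic variant filtering cascade
    with platform-specific rules, mutation burden per megabase, 96-channel
    trinucleotide mutational signature refitting and de novo discovery by
    non-negative matrix factorization, copy-number segment calling with
    fraction-of-genome-altered and profile-type classification, recurrent
    region comparison between groups, structural variant classification
    including fold-back inversions, a cross-tumor-type genetic event
    taxonomy, and cohort statistics (prevalence, Fisher co-occurrence,
    ANOVA with Tukey post-tests, Kaplan-Meier and logrank survival). A
    synthetic cohort generator with ground-truth labels makes every stage
    testable without access to restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    pracma,
    ape,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
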