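Package: epiclass
Title: Integrative Methylome and Mutation Subtyping of Urothelial Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus clustering of DNA methylation array beta values with an
    explicit hypermethylation signature rule, promoter methylation gene calling,
    somatic mutation load, mutual exclusivity and signature-exposure analysis,
    NMF clustering of exposure profiles, and survival association for urothelial
    carcinoma cohorts. Ships a synthetic multi-omics cohort generator that
    emulates the data structure of a two-subtype methylome study (planted
    hypermethylated probe blocks, driver mutation frequencies, trinucleotide
    signature mixtures, cluster-dependent hazards) together with the ground
    truth needed for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    mclust,
    pracma,
    withr,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
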