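Package: cdescan
Title: Detecting Cancer Driver Mutations Selected During CRISPR-Cas9 Editing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired CRISPR-Cas9 and shRNA viability screens to
    identify CRISPR-specific differentially essential (CDE+/CDE-) genes of a
    cancer driver, and a genome-wide scan ranking candidate drivers whose
    pre-existing mutant cells gain a selective advantage during Cas9 editing
    (CRISPR-selected cancer drivers, CCDs). Includes copy-number confound
    filtering, hypergeometric and permutation gene-set enrichment (with
    fragile-site and open-chromatin positional gene sets), a clinical
    logistic interaction model linking copy-number alteration burden of CDE+
    genes to driver mutation accumulation with tumor stage, Cas9-activity
    association tests, mutant-allele-frequency expansion analysis of
    parental versus Cas9-expressing cell lines, pooled isogenic sgRNA screen
    analysis with gold-standard quality control, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
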