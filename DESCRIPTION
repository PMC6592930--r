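Package: altiscan
Title: Population-Contrast Variant Analysis and Selection Scans for
    Two-Ecotype Resequencing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of whole-genome variant calls
    from two populations (for example highland versus lowland ecotypes):
    differential and common variant extraction under carrier-fraction
    thresholds, novelty flagging against a known-variants database,
    coding-consequence classification from genome FASTA and GFF3
    annotation, variant-type distribution tests (Fisher exact,
    per-chromosome chi-square), a Weir-Cockerham F_ST sliding-window
    selection scan with offline hypergeometric gene-set enrichment,
    per-chromosome variant density ("standard frequency") profiling with
    dense-region detection, mitochondrial variant accounting,
    replication-cohort validation, and population-structure and phenotype
    classification (Nei standard distance, UPGMA, multiple correspondence
    analysis of genotypes, PCA plus linear discriminant analysis).
    Includes a self-contained synthetic-study generator with planted
    selective sweeps for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    MASS,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
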