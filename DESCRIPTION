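Package: craniovar
Title: Rare-Variant Stratification, Gene Burden, and Family Genetics for
    Craniosynostosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging candidate gene variants in craniosynostosis
    cohorts and for the downstream cohort and family statistics. Implements
    the maximum-credible-allele-frequency framework (prevalence, genetic and
    allelic heterogeneity, inheritance model, penetrance), popmax-style
    AF_max assignment from gnomAD-like per-population allele counts, an
    in-silico predictor ensemble deleteriousness score (DS, range 0-6), and
    the joint rare-plus-damaging filter. Downstream: suture-class prevalence
    tables, loss-of-function burden enrichment against a reference
    population (Fisher's exact test), subtype contrasts, pedigree
    transmission summaries, sib recurrence and penetrance estimation, the
    transmission disequilibrium test, and a two-locus (major gene by common
    modifier SNP) association with table merging. A seeded synthetic-cohort
    generator produces variant tables and pedigrees with known ground truth
    so every stage is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
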