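Package: cnvmort
Title: CNV Calling, Burden and Mortality Association for SNP-Array Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls copy-number variants (CNVs) from SNP-array log R ratio
    and B allele frequency signals with a distance-aware hidden Markov
    model, applies per-sample quality control (LRR noise, call count,
    genomic wave), merges per-sample calls into cross-sample CNV regions by
    reciprocal-overlap transitive closure, computes per-individual CNV
    burden (count, average length, total length), tests burden covariates
    and region carrier status against prospective mortality with a
    left-truncated Cox proportional-hazards model on the age timescale, and
    pools per-study hazard ratios by inverse-variance fixed-effect
    meta-analysis.  Includes a synthetic-cohort generator (marker maps,
    intensity signals with implanted CNVs, Gompertz survival outcomes with
    known effects) so the full pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
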