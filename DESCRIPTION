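Package: famrvar
Title: Family-Based Rare-Variant Prioritization in Multiplex Pedigrees
Version: 0.1.0
Authors@R: person("famrvar", "maintainers", email = "devnull@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing rare, damaging variants in multiplex
    disease pedigrees, modeled on family-based inflammatory bowel disease
    studies in founder populations. Provides pedigree and VCF ingestion,
    genotype/variant/sample quality control (allele balance, Hardy-Weinberg,
    kinship classification, ancestry ellipsoids), damaging-variant filters,
    linkage-locus support (SNP map construction, pedigree trimming,
    contributing-family filters), within-family sharing and segregation rules
    with exact conditional transmission probabilities, gene-dropping
    enrichment simulation with empirical p-values and power, case/control
    replication statistics with simulation-based power, correlation-informed
    multiple-testing correction, a CMC gene-burden test, and a synthetic-data
    generator so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
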