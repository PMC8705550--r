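Package: oxiscore
Title: Genetics-Driven Drug Repositioning for Oxidative-Stress Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links disease GWAS hits to candidate drug targets through
    molecular quantitative trait loci (QTLs) and linkage disequilibrium,
    scores targets with a five-criterion genetic prioritization scheme,
    and selects existing drugs whose mechanism of action matches the
    direction of effect implied by the risk allele, gated by ADME-Tox
    descriptor rules for CNS penetration and oral bioavailability.
    Includes a two-locus EM haplotype-frequency estimator for LD and
    allele coupling, a synthetic-data generator with planted ground
    truth for end-to-end testing, and a bundled multiple-sclerosis /
    oxidative-stress case-study fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
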