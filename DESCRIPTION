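Package: apoedem
Title: APOE Genotype, Dementia Risk and Population Attributable Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating the association between APOE epsilon
    haplotypes and all-cause dementia in cohort data: calling epsilon
    diplotypes from phased genotypes at rs429358 and rs7412, genotype
    count and carrier-frequency descriptives with an exact binomial
    carrier-enrichment test, Cox proportional-hazards and logistic
    genotype association models with genotypic, additive and dominant
    codings, stratified-exposure population attributable fractions with
    an allele-level epsilon3/epsilon4 decomposition and bound-propagated
    confidence intervals, and a phenome-wide association screen with
    Bonferroni and false-discovery-rate control. A synthetic-cohort
    generator reproduces the statistical structure these analyses assume
    (haplotype frequencies, two-population ancestry mix, proportional
    hazards dementia onset with administrative censoring, lipid traits
    with per-allele effects) so the full pipeline runs without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
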