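# apoedem

Estimating the effect of APOE genotype on all-cause dementia risk, and
how much dementia is attributable to it, in cohort data.

The three common APOE isoforms (ε2, ε3, ε4) are defined by the phased
bases at two coding variants on chromosome 19 — rs429358
(chr19:44908684, T>C) and rs7412 (chr19:44908822, C>T; GRCh38): T–T is
ε2, T–C is ε3, C–C is ε4 (C–T is the rare ε1). `apoedem` implements the
full analysis chain around that map for genetic-epidemiology users:

* **Diplotype calling** from phased VCF genotypes, with strict REF/ALT
  orientation checks, an explicit policy for unphased double
  heterozygotes, and flagged handling of ε1.
* **Descriptives**: genotype/dose count tables, carrier proportions, and
  an exact two-sided binomial test of carrier enrichment against an
  external reference proportion.
* **Association models** on an age-from-origin survival clock: Cox
  proportional hazards (genotypic / additive / dominant codings, Efron
  ties), logistic sensitivity models, Kaplan–Meier curves by ε4 dose,
  Schoenfeld proportional-hazards diagnostics, gender-stratified and
  over-60 sensitivity configurations.
* **Population attributable fractions** by stratified exposure with the
  rare ε2/ε2 genotype as reference: per-stratum
  `PAF_g = CF_g · (OR_g − 1)/OR_g` (case-load form), joint PAF summed
  over the five ε3/ε4-containing genotypes, an allele-level ε3/ε4
  decomposition that splits the ε3/ε4 stratum with weight
  `w = R/(R+1)`, `R = OR(ε4/ε2)/OR(ε3/ε2)`, and bound-propagated
  confidence limits.
* **PheWAS**: every eligible trait (≥ 500 cases if binary, > 1000
  observations if quantitative) regressed on genotype with Bonferroni
  and Benjamini–Hochberg control.
* **A synthetic-cohort generator** reproducing the statistical structure
  the analyses assume (haplotype frequencies 0.104/0.852/0.044,
  two-population ancestry mix with PC confounding, exponential onset
  under genotype-specific hazard ratios, administrative censoring,
  lipid traits with per-ε4 effects), so the whole pipeline runs and is
  tested without access-controlled data.

See `vignettes/apoe-dementia-methods.Rmd` for the model, its
assumptions, and every numerical design choice.

## Worked example

```r
library(apoedem)

cfg <- sim_config(n_samples = 20000, baseline_hazard = 1e-3, seed = 2024)
coh <- simulate_cohort(cfg)
sum(coh$dementia_status)
#> [1] 657

tab <- summarize_genotypes(coh$diplotype, coh$dementia_status)
e4  <- carrier_stats(tab, "e4", "overall")
pct1(e4$prop_carrier); pct1(e4$prop_het); pct1(e4$prop_hom)
#> "19.5"  "18.5"  "1.0"

carrier_enrichment_test(e4$carriers, e4$n, 0.288)
#> [1] 2.82e-198

fit_cox(coh, survival_config())
#>    term    hr  hr_lo hr_hi        p n_events flag
#> 1 e2/e2 0.675 0.0948  4.81 6.95e-01      657   ok
#> 2 e2/e3 0.910 0.6583  1.26 5.71e-01      657   ok
#> 3 e2/e4 1.634 0.8116  3.29 1.69e-01      657   ok
#> 4 e3/e4 1.642 1.3736  1.96 5.09e-08      657   ok
#> 5 e4/e4 2.379 1.3956  4.05 1.45e-03      657   ok
```

Reading the output: 19.5% of the simulated cohort carries at least one
ε4 allele — far below the 28.8% external reference, hence the
astronomically small enrichment p-value. The genotypic Cox model
(adjusted for age at recruitment, gender, PCs 1–10 and ancestry, ε3/ε3
reference) recovers the dose-dependent risk gradient the cohort was
simulated under: hazard ratios rise from ~0.9 for ε2/ε3 through 1.64
for ε3/ε4 to 2.38 (95% CI 1.40–4.05) for ε4/ε4, with the wide ε2/ε2
interval reflecting that genotype's rarity.

A full run — simulate, call diplotypes from the written VCF, describe,
associate, PAF, PheWAS, report — is one call:

```r
bundle <- run_pipeline(pipeline_config(sim = sim_config(seed = 1),
                                       out_dir = "run1"))
```

or from a shell via the thin CLI
(`inst/scripts/apoe_pipeline.R run-all --seed 1 --out run1`), which also
offers `simulate`, `call-apoe`, `describe`, `associate`, `paf` and
`phewas` verbs plus YAML configs.

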