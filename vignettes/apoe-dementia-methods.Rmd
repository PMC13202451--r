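---
title: "Methods: APOE genotypes, dementia risk and attributable fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APOE genotypes, dementia risk and attributable fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoedem)
```

## The scientific problem

The APOE gene is the strongest common genetic risk factor for sporadic
dementia. Its three common isoforms — the ε2, ε3 and ε4 haplotypes — are
fully determined by the phased bases at two coding variants on chromosome
19 (GRCh38): rs429358 (chr19:44908684, T>C) and rs7412 (chr19:44908822,
C>T). The map is

| rs429358 | rs7412 | haplotype |
|---|---|---|
| T | T | ε2 |
| T | C | ε3 |
| C | C | ε4 |
| C | T | ε1 (rare) |

`apoedem` implements the full analysis chain for estimating how APOE
diplotypes affect all-cause dementia risk in a cohort with linked health
records: diplotype calling from phased genotypes, descriptive genotype
and carrier statistics, Cox and logistic association models, a
stratified-exposure population attributable fraction (PAF) with an
allele-level ε3/ε4 decomposition, and a phenome-wide screen. Because
population-scale cohort data are access-controlled, the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analyses assume, so every stage is testable end to end.

Throughout the package the ASCII labels `e2`, `e3`, `e4` (and `e1`)
denote the ε haplotypes, and a diplotype is the canonically ordered
unordered pair, e.g. `"e3/e4"`.

## Diplotype calling

Phase matters: an individual heterozygous at both sites is `e2/e4` if T–T
and C–C travel on the two chromosomes, but `e1/e3` if the bases pair as
C–T and T–C. `read_phased_genotypes()` therefore requires phased (`|`)
genotypes by default, locates the two sites by chromosome and position
(identifier as fallback) and refuses REF/ALT orientation mismatches
outright — a silent allele flip would invert every call. Unphased
double heterozygotes can be resolved by the `"assume-e2e4"` policy, which
is exact when the e1 frequency is zero (the competing phase requires an
e1 haplotype); the policy warns on every use. e1 carriers are called,
flagged, and excluded from the association stages by default: a
three-haplotype analysis has no e1 category, and silent misclassification
is worse than exclusion. Samples missing either site on either
chromosome are excluded listwise with a logged count, mirroring
complete-case analysis.

## The synthetic cohort

`sim_config()` holds every generative parameter. Defaults are the study
conditions of a large British South Asian community cohort of 51 104
adults:

* haplotype frequencies ε4 = 0.104, ε3 = 0.852, ε2 = 0.044 (drawn
  i.i.d., so diplotypes are in Hardy–Weinberg proportions). The printed
  source frequencies (10.4/85.1/4.4) sum to 99.9% after rounding; the
  remainder is assigned to ε3, the most common haplotype.
* a two-population ancestry mix (58.7% / 41.3%), with PC1 mean-shifted
  by ±1 SD by ancestry. The shift is deliberate confounding: it gives
  covariate adjustment something to do, so tests can detect a model
  that silently drops the PCs.
* dementia onset at age `16 + Exponential(rate = λ·exp(βg))`, with
  `βg` the diplotype's true log hazard ratio (defaults: 2.7 for e4/e4,
  1.5 for e3/e4, 1.6 for e2/e4, 0.8 for e2/e3 and e2/e2, 1 for the
  e3/e3 reference). A constant baseline hazard from age 16 is the
  simplest model satisfying proportional hazards *exactly*, which makes
  hazard-ratio recovery a clean acceptance surface.
* administrative censoring at a fixed calendar date (December 2024,
  encoded 2024.92) at age `censor_date − birth_year`.
* recruitment ages log-normal with median 39 and IQR 17.5 years
  (matching the control demographics of the emulated cohort), recruited
  uniformly over 2015–2020; gender Bernoulli(0.553 female).
* lipid-like quantitative traits with per-ε4-allele effects of +0.15 SD
  (LDL, triglycerides), +0.12 SD (total cholesterol) and −0.10 SD
  (CRP), matching the known directions of APOE lipid associations; one
  null binary trait (prevalence 0.2) exercises the logistic path.

The default baseline hazard (3.3065 × 10⁻⁴ events/person-year) was
calibrated once, numerically, from the generator's own closed-form event
probability (`calibrate_baseline_hazard()`) so that the default cohort
yields roughly 600 events — the case load of the emulated study. All
randomness flows through deterministic per-stage sub-streams of one root
seed, so toggling one stage never shifts another stage's draws and the
same config is byte-reproducible.

What the generator does **not** emulate: linkage disequilibrium beyond
the two APOE sites, genotype imputation error, differential
ascertainment of cases, age-varying (non-proportional) hazards,
competing mortality, or the masked small cells of published tables.
Passing tests therefore demonstrate that the estimators recover known
truth under the model's own assumptions — not that those assumptions
hold in any real cohort.

## Survival-time construction and association models

The survival clock is age from a fixed origin: 16 years in the primary
configuration (cohort members enter the study population at 16), 60 in
the sensitivity configuration, which also drops samples recruited at or
before 60 and cases diagnosed before 60. Cases contribute
`age_at_diagnosis − origin`; controls are censored at
`censor_date − birth_year − origin`. Two deliberate replications of the
emulated analysis deserve flagging:

* **No left truncation by default.** Entering everyone at the origin
  rather than at recruitment induces immortal person-time for a
  recruited cohort. The replicated construction is kept as the default;
  `left_truncation = TRUE` enters samples at recruitment age instead.
  Both behaviours are provided rather than silently "fixing" one.
* **Age at recruitment as a covariate on an age-based clock.** The
  emulated models adjust for recruitment age even though the time axis
  is age; the default covariate set keeps this, and dropping the
  covariate from `survival_config(covariates = ...)` removes it.

`fit_cox()` uses `survival::coxph()` with Efron tie handling,
convergence tolerance 10⁻⁸, at most 200 iterations and zero-initialised
coefficients. Codings: genotypic (each diplotype vs the configurable
reference, e3/e3 by default), additive (ε4 dose 0/1/2) and dominant
(any-ε4). Genotype categories with no events, or with standard errors
large enough to indicate separation, are flagged rather than dropped —
the published analyses hit exactly this with the rare e2/e2 reference.
Gender-stratified analyses are separate per-stratum fits (not a strata
term), matching the emulated design. `fit_logistic()` mirrors the same
interface with `stats::glm()`. Kaplan–Meier curves by ε4 dose use
`survival::survfit()` (Greenwood variance), and proportional-hazards
diagnostics use scaled Schoenfeld residual tests (`survival::cox.zph`),
skipped below 10 events.

## The attributable-fraction engine

The PAF stage answers: *what fraction of dementia cases would not have
occurred if every genotype stratum had the reference stratum's risk?*
With the rare protective ε2/ε2 genotype as reference (so that
intermediate-risk ε3 carriers are not absorbed into the reference), each
exposed stratum g ∈ {e3/e3, e3/e4, e2/e3, e2/e4, e4/e4} contributes

$$\mathrm{PAF}_g = \mathrm{CF}_g \cdot \frac{\mathrm{OR}_g - 1}{\mathrm{OR}_g},$$

where CF_g is the stratum's case fraction (cases with genotype g / all
cases) and OR_g its odds ratio vs ε2/ε2, treated as a risk-ratio
approximation for the rare outcome. The joint PAF sums the five exposed
strata. A printed variant of this formula circulates with the case
fraction in the denominator, `(OR−1)/(OR·CF)`; that arrangement exceeds
1 for small case fractions and is not a fraction of cases. The
case-load form above is the method's standard (Miettinen/Hanley) form
and is the package default; the literal arrangement is kept behind
`formula = "literal"` purely for auditability. With risk ratios and
exact case fractions the case-load form is an identity:
`joint PAF = (observed cases − expected cases under reference risk) /
observed cases`, which the test suite verifies on an enumerable
population.

The ε3/ε4 stratum carries one copy of each risk allele, so its PAF is
split between the alleles with weight

$$w_{\varepsilon 4} = \frac{R}{R + 1}, \qquad
  R = \frac{\mathrm{OR}_{\varepsilon4/\varepsilon2}}{\mathrm{OR}_{\varepsilon3/\varepsilon2}},$$

the ε4 share growing with ε4's relative effect. The ε2/ε4 stratum is
attributed wholly to ε4 and ε2/ε3 wholly to ε3 (only the doubly-exposed
stratum is split) — a modelling choice inherited from the emulated
method. Because the split is convex, `paf_e4 + paf_e3` equals the joint
PAF to machine precision; this conservation is fuzz-tested over random
stratum tables.

Confidence bounds re-evaluate each stratum's PAF at
`exp(log OR ∓ 1.96·se)` and sum them; decomposition bounds use the
ratio's own bounds with `se(log R) = sqrt(se₄² + se₃²)`. This treats
strata as independent and is a bound propagation in the emulated
method's own style, not a delta-method CI — with a nearly-empty
reference stratum the bounds are extremely wide, which is honest about
where the information is.

## The phenome-wide screen

Every binary trait with ≥ 500 cases and every quantitative trait with
> 1000 non-missing observations is regressed on genotype (vs e3/e3)
with the primary covariate set — logistic for binary, linear for
quantitative. The test count m is frozen at eligibility time; failed
fits keep their slot (no data-dependent threshold inflation).
Quantitative traits are analysed untransformed by default.

Multiplicity is controlled two ways. The default unit is the *trait*
(`m` = eligible traits, the `0.05/m` convention of the emulated study):
a term passes Bonferroni when its p-value beats `α/m`, and
Benjamini–Hochberg runs on the per-trait minimum p-values, each trait's
terms inheriting its flag — which guarantees the invariant that the
Bonferroni-flagged set is a subset of the FDR-flagged set. Note that
with five genotype terms per trait the trait-level unit makes about 5α
of family-wise error under a global null: the Bonferroni guarantee
attaches to the number of comparisons actually made, not to the number
of traits. `multiplicity_unit = "term"` counts trait × genotype tests
and restores the ≤ α guarantee; the null-calibration test in this
package's suite uses that unit for exactly this reason.

## Numerical and design choices

* Exact binomial carrier-enrichment test: two-sided by the
  minimum-likelihood convention (`stats::binom.test`), summing all
  outcome probabilities no larger than the observed one. The external
  reference proportion (e.g. 28.8% ε4 carriage in a European-ancestry
  biobank) is a plain numeric parameter, never re-derived.
* Count tables store full precision and render percentages at one
  decimal (`pct1()`); masked cells are `NA` and propagate, with the ε4
  dose rows standing in where they can.
* Degenerate inputs: empty groups warn; an all-reference cohort fits no
  genotype terms; constant covariates are dropped with a message; a
  genotype category with zero events is flagged non-estimable.
* Problem sizes in the test suite were chosen to keep each property
  informative at desk scale: frequency/HWE checks at n = 100 000
  haplotype draws, hazard-ratio recovery at the full cohort size
  (n = 51 104, 20 replicates), null calibration over 200 fits of
  n = 10 000 cohorts with the baseline hazard raised to keep ~600
  events, CI-coverage over 200 replicates at n = 4 000, and the
  family-wise-error simulation over 200 seeds of 236 null traits at
  n = 1 050. All stochastic assertions use 3-standard-error bands
  around their expectation under fixed seeds.

## Known limitations

The published attributable fractions for the emulated cohort (ε4 ≈ 13%,
ε3 ≈ 36%, joint ≈ 49% — with the same study's discussion elsewhere
quoting 42.9% for the joint figure, a discrepancy this package
documents but does not adjudicate) rest on fitted odds ratios against a
reference genotype carried by ~0.3% of the population, only some of
which are printed. They are therefore reproducible only qualitatively:
simulations at full cohort scale with the reported genotypic effects
place the ε4-attributable fraction in the low tens of percent with a
lower bound below zero, and that qualitative band — not the exact
printed values — is what the acceptance suite asserts. Real-data
features the generator does not model (ascertainment, non-proportional
hazards, imputation error) are listed above; conclusions about real
cohorts require real data.
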