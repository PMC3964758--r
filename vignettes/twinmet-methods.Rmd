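---
title: "Models and simulation design in twinmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation design in twinmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmet)
```

twinmet implements a complete analysis chain for candidate-gene studies of
leisure-time exercise behavior in twin-family samples: phenotype scoring,
genotype coding and quality control, kinship-aware mixed-model association,
and a Monte-Carlo power engine built on a synthetic twin-family generator.
This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and — importantly — what the synthetic
data do and do not emulate.

## The phenotype: weekly MET hours

Exercise surveys record, per activity, how many years and months per year
a participant took part, weekly frequency, and minutes per session. The
score is

$$\mathrm{MET\ hours/week} \;=\; \sum_{\text{activities}} \mathrm{MET}
\times \frac{\text{sessions}}{\text{week}} \times
\frac{\text{minutes}}{60},$$

after three filters that isolate *regular leisure* exercise: the activity
must be leisure-time (no transportation, gardening, house cleaning or
compulsory PE), practised at least 3 months a year, and for at least half a
year. The sum is truncated at 120 MET hours (a level around 17 hours of
vigorous sport per week; values above it are rare and dominated by
reporting error). MET values come from a shipped lookup table with separate
youth (< 18 years) and adult (18+) columns, reflecting the convention of
using a youth energy-expenditure compendium for minors and an adult
compendium otherwise; the table is a curated ~35-sport subset and is
user-replaceable by CSV. Unknown activities raise an error rather than
defaulting — a silent default MET would bias scores invisibly.

Longitudinal records are merged to one score per person: reports above age
50 are discarded, waves completed while injured are dropped, and the
remaining record is chosen adult-first (most recent adult wave, else most
recent adolescent wave at ages 13–17, else most recent child wave).
"Most recent" is survey-wave order; because wave identifiers may tie or be
non-numeric, ties break by higher age at survey, then lexical wave id.
Adolescence is defined as 13–17 at survey, the age from which self-report
replaces parental report.

## Genotype coding and QC

SNPs are coded additively as copies (0/1/2) of a designated counted allele.
VNTRs are multi-allelic, so they are coded as copies of one focal repeat
(e.g. the 7-repeat of the *DRD4* exon-III VNTR, the 148-bp allele upstream
of *DRD5*, the 480-bp allele of *DAT1*); any pair of non-focal repeats
codes 0.

QC metrics and default thresholds mirror standard pre-imputation filters:
folded MAF > .01, Hardy-Weinberg p > 1e-5, Mendelian error rate < .02,
call rate > .95, reference allele-frequency difference < .20, duplicate
concordance ≥ .95. Choices worth noting:

* **HWE test.** The default is the Pearson chi-square with 1 df and no
  continuity correction, computed from genotype counts at the sample allele
  frequency; the conditional exact test (summing heterozygote-count
  probabilities no more likely than the observed one) is available via
  `method = "exact"` for small or rare-allele samples. A monomorphic sample
  returns p = 1 by convention. For VNTRs, HWE is assessed on the
  focal-vs-rest biallelic collapse, matching the single focal-repeat
  coding.
* **Dosages.** `maf()` accepts dosages (mean dosage / 2); `hwe_test()` and
  `mendel_check()` refuse them with an explicit error, since genotype-class
  counts and transmission logic require hard calls.
* **Missing data.** Complete-case per variant; the polygenic risk score is
  complete-case across its variants (an individual missing any included
  variant has a missing score), so per-model sample sizes are always
  reported and auditable.
* **Risk score.** The score sums copies of each variant's hypothesized
  dopamine-*increasing* allele. The shipped mapping
  (`inst/extdata/effect_alleles.csv`) expresses every hypothesis relative
  to the counted allele (`counted` adds the code, `opposite` adds
  2 − code, which also covers "absence of the focal repeat" hypotheses).
  The file is editable, and the orientation used is part of the output
  provenance.

## The mixed model

All association tests use

$$y = X\beta + a + e, \qquad a \sim N(0,\, \sigma^2_a A), \qquad
e \sim N(0,\, \sigma^2_e I),$$

with $A$ the additive genetic relationship matrix: twice the kinship
coefficient, computed by the tabular method family by family, with MZ
co-twins treated as genetically identical (mutual entry 1, identical rows).
$A$ is block-diagonal by family, symmetric and positive semi-definite.
The default fixed effects are intercept, sex (0 = male, 1 = female), age as
a z-score standardized on the analysis sample, the sex × age interaction,
and the variant code(s) or risk score; confounder covariates (ancestry or
batch components, platform dummies) enter as ordinary user-supplied
columns.

**Estimation.** Maximum likelihood, matching the convention of comparing
nested models by likelihood ratio (REML likelihoods are not comparable
across fixed-effect structures; REML is available as an option for variance
reporting). The variance ratio $\lambda = \sigma^2_a/\sigma^2_e$ is
profiled: each family block of $A$ is eigendecomposed once
($A = U D U'$), the data are rotated by $U'$, and for fixed $\lambda$ the
GLS $\hat\beta$ and $\hat\sigma^2_e$ are closed-form, leaving a 1-D search
over $\log\lambda$ (Brent, interval $[-15, 10]$, tolerance 1e-8 — wide
enough for heritabilities up to 0.9999 and effectively zero). Each
likelihood evaluation is $O(n)$ because the rotated covariance is diagonal,
and the decomposition is reused across fits and simulation replicates on
the same pedigree. The boundary $\sigma^2_a = 0$ is evaluated explicitly;
ties (within 1e-7 log-likelihood units, e.g. when $A = I$ makes the profile
exactly flat) resolve to the boundary, and a boundary flag is reported
rather than hidden. Standard errors come from the inverse GLS information
at the ML variance estimates.

**Tests.** Single coefficients use two-sided Wald chi-square tests
$(\hat\beta/SE)^2 \sim \chi^2_1$; joint tests of several variants use the
likelihood-ratio chi-square with df = number of added terms, requiring both
fits to be ML on the same complete-case sample. The default alpha is
$.05/11 \approx .0045$, the Bonferroni correction for a panel of eleven
candidate variants. Whether historical analyses of this design used Wald or
LRT for single variants is not documented; the two are asymptotically
equivalent here and the package exposes both.

## The synthetic twin-family generator

The generator provides the sampling frame for the power engine and for all
calibration tests. Design choices, each of which was genuinely open:

* **Family templates and mixture.** Families are drawn from four templates
  — MZ twin pair, DZ twin pair, DZ pair + one full sibling, singleton —
  with default weights .325/.325/.30/.05. The weights were calibrated once
  so the mean number of *analysed* individuals per family is exactly 2.25,
  the ratio seen in a register of 8,768 participants in 3,900 families,
  while keeping the sample twin-pair-dominated with equal MZ/DZ shares and
  few singletons. Exact register composition is unpublished, so the
  mixture is a declared assumption and is user-configurable. Counts are
  allocated by largest-remainder rounding plus a minimal repair so both
  the family total and the individual total are met exactly whenever
  feasible (always within one template size).
* **Parents as implicit founders.** Twin and sibling templates include the
  two parents as unsampled founders: they supply alleles for gene dropping
  and Mendelian checking but are excluded from the analysis sample, which
  represents participants rather than full ancestries.
* **Ages and sexes.** Adult templates draw a family age uniformly on
  [18, 50] (co-twins share it; a sibling is offset by 2–4 years, clipped);
  MZ pairs share sex. The power engine deliberately omits age/sex from its
  fits, so these attributes matter only when a user opts into covariate
  models.
* **Gene dropping.** Founders draw allele counts Binomial(2, MAF) — i.e.
  Hardy-Weinberg proportions; each child receives one allele per parent,
  a Bernoulli draw with probability half the parent's count (exact for
  unphased biallelic transmission); MZ co-twins copy one draw. Every
  simulated dataset is Mendelian-consistent by construction, and the test
  suite asserts this with the independent transmission checker.
* **Phenotype.** A latent unit-variance score
  $y_0 = b\,(g - 2p) + \sqrt{h^2}\,a + \sqrt{1 - R^2 - h^2}\,e$, with
  $b = \sqrt{R^2 / 2p(1-p)}$ so the variant explains exactly $R^2$ of the
  latent variance, and $a$ drawn with covariance $A$ via the same
  family-block decomposition. The score is mapped to mean 13 and SD 18 MET
  hours, floored at 0 and capped at 120. This reproduces the right skew of
  exercise scores by censoring (about a quarter of simulated participants
  land on 0) without inventing an unstated parametric family. Heritability
  defaults to $h^2 = 0.55$, the midpoint of the 50–60% range reported for
  adult exercise behavior by twin studies. With the floor and cap disabled
  the empirical mean/SD converge to the configured values — a property the
  tests check, and the setting used for heritability-recovery experiments
  (truncation attenuates $\hat h^2$, which is a feature of the emulation,
  not an estimator defect).
* **Seeds.** Every public simulation function takes a seed. The power
  engine draws one vector of per-replicate seeds under its master seed
  (`sample.int(2^31 - 2, n_reps)`), so any single replicate can be
  reproduced in isolation and runs are bit-identical under a fixed master
  seed.

## The power engine

Each run generates one pedigree (family composition is a nuisance; holding
it fixed across replicates removes a variance component irrelevant to the
question), then per replicate: gene-drop, simulate the phenotype, fit the
mixed model with intercept and variant only, and record the variant's Wald
p-value. Power is the fraction of replicates with p < alpha; the 95%
confidence interval is the normal-approximation binomial interval
$\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$ (Wilson available as an
option). Sex and age are excluded from the power fits, making estimates
conservative in the sense that real analyses adjust for them. Replicates
whose fit fails are logged and excluded; a run with more than 5% failures
is declared invalid rather than silently reported.

Two limit-case oracles validate the engine: with singleton families and no
truncation, empirical power matches the closed-form noncentral chi-square
approximation with NCP $= N R^2/(1-R^2)$; and under a null effect the
rejection rate matches the nominal alpha (checked at 10,000 replicates,
N = 2,000 — the type-I error of the whole simulate-and-fit chain, not just
of the test statistic).

## What the generator does not emulate

Passing calibration tests shows the *engine* is correct under its own
assumptions; it does not make the assumptions true of real questionnaire
data. In particular:

* **The marginal distribution of real scores.** Real exercise data are
  strongly zero-inflated — commonly around half of register participants
  report no regular leisure exercise — and skewed beyond what a censored
  Gaussian with mean 13 / SD 18 produces (zero mass ≈ 24%). Because
  censoring attenuates the genotype-phenotype correlation, the effective
  noncentrality at a given nominal $R^2$ depends steeply on this zero
  mass: rejection rates computed under this generator should be read as
  upper-range estimates for heavily zero-inflated real phenotypes, and
  power for the same design computed under different distributional
  recipes can be substantially lower (at N ≈ 2,000 and $R^2$ = .005 the
  difference can exceed 0.1 in absolute power).
* **Ascertainment and composition.** Real registers include parents and
  spouses as participants, related extended families, and age-structured
  participation; the generator's four templates and uniform adult ages are
  a simplification.
* **Linkage disequilibrium and measurement.** Variants are simulated
  independently (no LD), genotypes without error, and the phenotype
  without reporting error beyond truncation.

## Problem sizes used in the shipped tests

The test suite was sized for routine re-running: calibration checks use
2,000–30,000 simulated individuals where moment accuracy is needed and a
few hundred elsewhere; the type-I check uses 10,000 replicates at
N = 2,000; heritability recovery averages 200 replicates; the power grid
runs the four design points (N = 2,152–8,756) at 1,000 replicates each,
matching the replicate count conventional for this design. The
`scripts/acceptance.R` driver re-runs exactly that grid from a single
command-line seed.

## Known limitations

* The mixed model is Gaussian; no generalized (e.g. hurdle or Tobit)
  response models, which would be the natural next step for zero-inflated
  scores.
* Pedigrees beyond twins/siblings/parents/spouses (multi-generation
  extended families) are supported by the relationship-matrix code but not
  by the generator's templates; X-linked inheritance is not modelled.
* The Wald/LRT inference is asymptotic; no small-sample denominator-df
  corrections are applied (immaterial at the sample sizes this package
  targets).
* Imputation, haplotype phasing and ancestry principal components are
  upstream of this package: dosages are accepted where statistically
  meaningful, and ancestry covariates enter only as user-supplied columns.
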