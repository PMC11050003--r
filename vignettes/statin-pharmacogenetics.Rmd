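---
title: "Methods: SLCO1B1 statin pharmacogenetics, GMTE triangulation and avoidable events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SLCO1B1 statin pharmacogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`statinpgx` implements a pharmacogenetic analysis pipeline for statin
response driven by *SLCO1B1* variation, together with a synthetic-cohort
generator that emulates the statistical structure such an analysis assumes.
The pipeline covers: star-allele and haplotype calling from unphased exome
genotypes; rule-based gene risk scores; covariate-adjusted association scans
(linear for biomarkers, proportional hazards for GP-record outcomes, with
Benjamini–Hochberg control for the rare-variant scan); triangulation of the
genetically moderated treatment effect (GMTE) across an estimator family
gated by Cochran's Q; and the conversion of a per-year risk difference into
avoidable adverse-event counts.

The numbered scripts under `analysis/` are thin narrative drivers over the
package functions; every computation they perform is exported, unit-tested
API.

## Genotypes and star alleles

Exome genotypes are unphased, so multi-variant star alleles (*15 = *5 + *37,
*14, *20) cannot be resolved into cis-haplotypes. The package therefore
calls them at **carrier level**: a sample is a carrier when it holds at
least one risk allele at *every* constituent site, and a member of the
haplotype's **reference group** when it holds zero copies at every
constituent site. Samples carrying some but not all constituent alleles
belong to neither group and are excluded from that haplotype's contrasts.
This matches how carrier-versus-reference haplotype analyses are reported in
practice, and it is conservative: carrier status is an upper bound on true
cis-carriage.

Definitions live in a shipped tab-delimited table
(`star_allele_definitions.tsv`), not in code, because star nomenclature
evolves (*1B was renamed *37). The shipped table uses rs4149056-C (*5),
rs2306283-G (*37), rs11045819-A (*4) and rs34671512-C (*19); *15 couples the
first two, *14 couples rs11045819-A with rs2306283-G (exactly those two
sites — some nomenclatures list further sites, and the two-site definition
is the package's pinned choice), and *20 couples rs2306283-G with
rs34671512-C, the pairing consistent with both current nomenclature and the
observed carrier fraction (a *20 carrier fraction of ~10.1% can only arise
from a site whose own carrier fraction is at least that large; rs34671512 at
~10.3% is the unique fit among the panel sites). The *45/*46 rows are
synthetic placeholders to be replaced with a current definition table.

The filtering cascade keeps variants with predicted HIGH/MODERATE impact and
minor allele count (MAC) **strictly greater** than 3, then splits at minor
allele frequency (MAF) 0.1% into common and rare sets. MAF is folded
(always ≤ 0.5); an all-missing variant yields flagged-undefined statistics,
never a silent zero.

## Gene risk scores

Both schemes share the homozygote branch: rs4149056-CC is high risk. The
heterozygote branch classifies a *5 heterozygote as high risk only when no
protective allele is carried — under GRS-1 that means rs2306283-AA,
rs11045819-CC and rs34671512-AA; GRS-2 replaces the rs2306283 condition with
GG (treating the G allele as acting with the detrimental *5 allele).
Heterozygous rs2306283 (AG) fails both homozygote predicates and is low
risk under either scheme; treating heterozygous protective alleles as
protective would be a different published scheme, and the rule table here
pins the homozygote-only reading. GRS-3 is GRS-2 plus carriers of a
configurable list of LDL-increasing rare variants. Missing genotypes give a
missing class — a risk classifier must not silently downgrade to "low".

## Association models

Baseline biomarkers use ordinary least squares with per-genotype categories
(het/hom versus wild type) or carrier coding, adjusted by default for age,
sex and five genetic principal components; assessment centre can be added
as a categorical covariate. Rank-deficient designs error naming the
collinear columns; contrasts with fewer than three carriers are flagged
unstable rather than suppressed.

Time-to-event outcomes use Cox proportional hazards (Efron ties) with entry
at first statin prescription, restricted to age 40+ at entry and at least
two months of prescriptions, optionally to ≥ 5 years on statins, excluding
prevalent cases. Discontinuation is labelled when the last prescription
falls ≥ 3 months before the censoring date (month-to-day conversion uses
365.25/12-day months).

The rare-variant scan runs per-variant carrier regressions with
Benjamini–Hochberg adjustment across the scanned set (via
`stats::p.adjust`), plus a combined any-carrier analysis and sex-stratified
estimates.

## The GMTE estimator family

Let $Y$ be the outcome, $T$ treatment, $G$ carrier status, $X$ covariates,
and $\pi$ the proportion treated. On the mean-difference scale:

* **GMTE1**: coefficient of $G$ in the adjusted model fitted to the treated;
* **GMTE0**: the same among the untreated (doubles as the no-direct-effect
  check);
* **RGMTE**: $\hat\beta_{1} - \hat\beta_{0}$ with
  $se = \sqrt{se_1^2 + se_0^2}$;
* **MR**: the whole-cohort coefficient of $G$ divided by $\hat\pi$, with the
  standard error scaled by $1/\hat\pi$ (intention-to-treat deflation: with
  no effect in the untreated, the whole-cohort association is $\pi$ times
  the GMTE);
* **CAT**: the apparent treatment coefficient among carriers minus that
  among non-carriers, from genotype-stratified adjusted fits.

Estimates on a common scale are pooled by inverse-variance weighting when
Cochran's $Q = \sum_i w_i(\hat\beta_i - \bar\beta)^2$, $w_i = 1/se_i^2$,
$df = k-1$, has $p > 0.05$ (configurable); otherwise the combination is
refused and the refusal propagates to downstream reports. All tests are
two-sided Wald; confidence intervals are $\pm 1.96\,se$ (log scale for
hazard ratios).

### A structural note on CAT versus RGMTE

Unadjusted, CAT and RGMTE are the *same* four-cell contrast:
$E[Y|T{=}1,G{=}1]-E[Y|T{=}1,G{=}0]-E[Y|T{=}0,G{=}1]+E[Y|T{=}0,G{=}0]$.
Any confounder of treatment that is independent of genotype shifts the two
treatment contrasts equally and cancels; homogeneous confounding by
indication therefore biases *neither* estimator asymptotically. The two
diverge through their different stratified adjustment: CAT's
treated-versus-untreated fits inherit the covariate composition of each
genotype stratum, so when the strength of indication-driven prescribing
varies along a measured axis that also predicts carrier frequency (e.g.
population structure across assessment centres), CAT's stratum-specific
confounding no longer cancels, while RGMTE's within-treatment genotype
contrasts remain clean ($U \perp G \mid T, Z$). The generator's
`confounded_treatment` scenario implements exactly this mechanism (severity
$U \sim N(0,1)$ raising LDL by 1 mmol/L per SD; prescribing logit slope on
$U$ of 1 in centre A and 4 in centre B; rs2306283 risk-allele frequency
raised by 0.4 in centre B), and the test suite verifies the designed
behaviour: CAT biased by more than twice its replicate SD, RGMTE within
half.

### Event outcomes: the additive rate scale

Per-year risk differences use an additive person-years rate model, not
proportional hazards, because the avoidable-events arithmetic
(rate × patient-years) is only coherent on the additive scale. Without
covariates each stratum estimate is the closed-form cell rate difference
with Poisson variance $\sum e / py^2$; with covariates an identity-link
Poisson model on person-year-scaled regressors is fitted (crude cell rates
as starting values). MR on this scale deflates the whole-cohort rate
difference by the person-year-weighted proportion treated. Cells with fewer
than five events trigger a normal-approximation warning. Whether the
original per-year risk differences came from an additive-hazards model or
another specification is not documented upstream; the identity-link
person-years model is this package's pinned choice.

## Avoidable events

`avoidable_events()` multiplies the per-year risk difference by carrier
patient-years, rounds **half away from zero** to whole cases (base R's
round-half-to-even would turn 64.5 into 64), caps at the observed carrier
case count with a warning, and reports percentage reductions to one decimal
plus rounded-integer forms (published figures mix the two styles; the
integer "3%" is the rounded 2.97% quotient, not a separately computed
number). The Q-gate refusal path produces an explanation object instead of
a report.

## The synthetic cohort generator

The generator is first-class, tested code; every study condition is a
configuration default chosen once:

* **Genotype structure.** Four-site haplotypes are factorised on the
  rs2306283 allele: each chromosome draws its rs2306283 risk allele with
  probability $p_{37}$, then each other site's risk allele with a
  conditional probability ($a_s$ on a G chromosome, $b_s$ on an A
  chromosome). Given per-site allele frequencies $p_s$ and a target carrier
  fraction $c_h$ for the coupled haplotype, the solution is closed-form:
  $P(\text{chromosome carries neither})^2 = c_h - 1 + (1-p_s)^2 +
  (1-p_{37})^2$, whence $b_s$ and $a_s$. Independent per-site draws cannot
  reproduce carrier fractions like 23.7% for *15 (independence gives
  ~16.5%); the coupling reproduces both the genotype frequencies
  (Hardy–Weinberg at the implied allele frequencies, matching the observed
  genotype tables to within sampling error) and the *15/*14/*20 carrier
  fractions (23.72%/23.71%/10.13%).
* **Treatment.** Bernoulli with $\pi = 0.6$ by default (the analysis needs
  a substantial untreated stratum; the exact treated share of the source
  population is not printed, and 0.6 is a realistic middle ground),
  independent of genotype unless the odds-ratio link or the indication
  machinery is switched on.
* **LDL.** Untreated baseline 3.90 mmol/L with a −1.15 mmol/L treatment
  effect, giving a treated mean of 2.75 mmol/L; residual SD 0.66; small
  sex/age/PC effects. Gene-by-treatment effects apply only to treated
  carriers (defaults: +0.02 *5-het, +0.08 *5-hom, +0.03 *15, −0.02 *4,
  −0.01 *14, −0.01 *20, +0.01 *37; rare variants +0.65 to +1.05);
  treatment-independent direct effects default to zero. Because *15
  carriers necessarily carry *5, marginal haplotype contrasts under the
  full default structure absorb the constituent-variant effects — exactly
  as marginal regressions on real data do. Recovery tests therefore inject
  one effect at a time.
* **Events.** Muscle-symptom times are exponential with hazard
  0.005/yr plus additive increments for treated carriers (+0.0008/yr *15,
  +0.0005/yr *20). Constant hazards make the additive rate scale exact and
  keep every estimator's target well-defined. Follow-up is gamma
  (mean 6.7, SD 4.7 years, truncated to 2 months–25 years);
  discontinuation is exponential at 0.038/yr (≈ 22% ever-discontinued over
  the mean follow-up); prescription dates and administrative censoring are
  emitted as ISO-8601 records. Rare-variant dosages are binomial at
  MAC-derived frequencies relative to a reference cohort size, so expected
  MACs scale with the simulated n.
* **Determinism.** One seed governs a single RNG stream; regenerating a
  fixture with its recorded seed reproduces the output files byte for byte.

What the generator does **not** emulate: cohort selection and volunteer
bias, GP coding behaviour, dose titration or switching, non-constant
hazards, linkage disequilibrium beyond the single coupling axis, and
genotype-calling error. Passing tests therefore demonstrate that the
pipeline recovers what it assumes, not that those assumptions hold in any
particular real cohort.

## Problem sizes and numerical choices

The replicated recovery checks run 50 cohorts of n = 10,000 per injected
effect (0, 0.03, 0.08 mmol/L) and require mean bias below half the
replicate SD for GMTE1/RGMTE/MR/CAT; the per-year rate pipeline is checked
on one n = 60,000 cohort against the injected 0.0008/yr within three
standard errors; null false-positive rates use 200 cohorts of n = 4,000
with binomial 99% bounds around 5%. These sizes are the package's chosen
compromise between Monte-Carlo precision and runtime. Other numerical
choices: two-sided Wald inference throughout; Efron tie handling; matrix
solves via QR (in `lm`) and Cholesky (in the rate model); rounding of case
counts half away from zero; 365.25-day years and 30.4375-day months.

## Known limitations

Carrier-level haplotype calls overcount true cis-haplotypes when both
constituent alleles are common; the MR deflation assumes all-or-nothing
treatment with no dose dimension; the identity-link Poisson fit can fail on
pathological covariate sets (the closed-form cell path has no such mode);
and the *45/*46 definitions are placeholders. The avoidable-events
illustration is a group-level accounting exercise — it does not support
individual treatment recommendations.
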