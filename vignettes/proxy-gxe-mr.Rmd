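---
title: "Proxy gene-by-environment Mendelian randomization: models, simulators and design choices"
author: "proxyGxEMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proxy gene-by-environment Mendelian randomization: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxyGxEMR)
```

## The scientific problem

Whether heavier maternal smoking in pregnancy shifts offspring towards
left-handedness is hard to answer observationally: early-life exposures are
confounded, self-reported, and entangled with each other. Mendelian
randomization (MR) replaces the exposure with a genetic instrument, but the
relevant genotype here is the *mother's* smoking-heaviness genotype, which
most biobanks never measured. The proxy gene-by-environment (GxE) design
works around this: the offspring's own genotype (a single variant in the
nicotinic-receptor region, or a polygenic risk score for cigarettes smoked
per day) proxies the maternal genotype, and the analysis is stratified on
whether the mother smoked in pregnancy.

The stratification carries the causal logic. In offspring of mothers who
smoked, the maternal genotype could act on the outcome through smoking
heaviness; in offspring of mothers who never smoked in pregnancy, that path
is closed, so any residual instrument--outcome association in the unexposed
stratum measures horizontal pleiotropy. Subtracting the unexposed-stratum
Wald estimate from the exposed-stratum one therefore yields a causal
estimate corrected for (stratum-constant) pleiotropy.

`proxyGxEMR` implements that whole pipeline -- observational regressions,
PRS construction, stratified Wald-ratio estimation with correction, control
checks -- together with a synthetic mother--offspring cohort generator and a
Monte-Carlo harness for power, calibration and collider-bias experiments.

## The generative model

`generateCohort(simParams(...))` simulates, per mother--father--offspring
trio:

1. **Genotypes.** Parental alleles are independent Bernoulli($p_j$) draws
   per SNP (Hardy--Weinberg), with haplotypes retained. Offspring receive
   one allele sampled uniformly from each parent, so
   $\mathrm{corr}(G_{\mathrm{mother}}, G_{\mathrm{child}}) = 1/2$ under
   random mating. An optional spousal correlation $s$ copies each paternal
   allele from the matching maternal allele with probability $s$; this
   keeps every marginal in HWE, makes the parental dosage correlation
   exactly $s$, and gives
   $\mathrm{corr}(G_m, G_o) = (1+s)/\sqrt{2(2+s)}$.
2. **Exposure.** Smoking initiation is Bernoulli on the logit scale with
   baseline `init_base`, an optional per-allele genetic term
   (`init_per_allele`, the collider pathway) and a latent standard-normal
   confounder $U$ (`conf_on_init`). Among smokers, cigarettes/day is
   `exposure_mean` $+ \sum_j w_j G_{mj}$ plus Gaussian noise, truncated at
   zero; non-smokers have no cigarettes/day value by construction.
3. **Outcomes.** Left-handedness is Bernoulli with logit
   `outcome_base_logit` $+ \beta_c \cdot \text{cigs} \cdot \text{smoked}
   + \beta_p \cdot G_o + \gamma U$: the causal path acts only through
   cigarettes actually smoked, the pleiotropic path acts through the
   offspring genome regardless. Birthweight, the negative-control outcome,
   is linear in the same exposure with its own $U$ loading.
4. **Covariates.** Sex, multiple birth, breastfeeding, birth year and
   month, country and Townsend deprivation are drawn from fixed marginals,
   independent of genotype.

### Defaults: the stated world

The defaults describe a UK-Biobank-like cohort: effect-allele frequency
0.33 (the frequency implied by the published genotype-class counts
44.89/44.23/10.88%), 30.6% of mothers smoking in pregnancy, a 9.82%
left-handedness base rate, mean birthweight 3.33 kg, 54.5% female
offspring, 2.25% multiple births, 71.2% breastfed, birth years centred on
1951, Townsend mean -1.53. The per-allele exposure weight (0.86
cigarettes/day) is chosen so the variant explains roughly 0.4% of
cigarettes/day variance among smokers, matching the published instrument
strength (R² = 0.004 for the single SNP, 0.005 for the PRS). All causal,
pleiotropic, collider and confounder paths default to zero.

Two generator choices are not stated in the source material and are fixed
here once:

* **`exposure_mean` (13.7 cigarettes/day, residual SD 9).** The exposure
  distribution among smokers is never specified. A zero-mean Gaussian
  truncated at zero would make truncation the dominant feature of the
  distribution, so a location parameter is included; ~14 cigarettes/day
  with SD ~9 is a realistic smokers' distribution for this cohort's era,
  and truncation then affects <10% of draws. The per-SD-to-per-cigarette
  effect conversion in the power module uses the analytic (untruncated) SD;
  the small (~7%) truncation-induced discrepancy is immaterial at the
  granularity of power statements.
* **Collider presets.** `colliderParams("initiation")` opens
  genotype→initiation (0.4 log-odds/allele) and U→initiation (0.8),
  U→handedness (0.5); `colliderParams("birthweight")` opens
  smoking→birthweight (-0.025 kg per cigarette/day), U→birthweight (0.3)
  and U→handedness (0.5). These magnitudes are chosen to make the
  qualitative mechanisms visible at n = 40,000--50,000; only signs and
  the marginal-versus-conditional contrast are scientifically meaningful.

The `init_per_allele` collider term is scaled per *effect allele* (matching
its definition) rather than per unit of the weighted exposure score; for
the default single-SNP world the two parameterizations differ only by the
constant $w$.

### What the generator does not emulate

No linkage disequilibrium beyond the r² estimable from a supplied dosage
panel, no imputation uncertainty (hard calls only), no X chromosome, no
missing data unless a mask is applied, no assortative-mating equilibrium
(the spousal-correlation model is a one-generation perturbation), and no
measurement error in reported maternal smoking. A green simulation test
therefore establishes internal statistical correctness of the estimators
under the stated model, not robustness to the reporting biases discussed
for real cohort data.

## The estimators

**Stratified associations.** `geneticAssociation()` fits logistic (binary
outcome) or linear (continuous) regressions of the outcome on the
instrument, complete cases only, optionally adjusted (the published
"model 2" adjusts for sex, year of birth and ten genetic principal
components; PCs are accepted as precomputed columns, not re-derived).

**Wald ratio.** $\hat\beta_{IV} = \hat\beta_{GY}/\hat\beta_{GX}$ with the
first-order delta-method standard error
$\sqrt{se_{GY}^2/\beta_{GX}^2 + \beta_{GY}^2 se_{GX}^2/\beta_{GX}^4}$ and
95% normal CIs. The numerator--denominator covariance is ignored (different
subsets); a weak-instrument warning fires below $|\beta_{GX}|/se_{GX} =
\sqrt{10}$ (the F < 10 convention); $\beta_{GX} = 0$ is an error rather
than an infinite estimate.

**Pleiotropy correction.** `pleiotropyCorrect()` subtracts the unexposed
from the exposed Wald estimate with
$se = \sqrt{se_1^2 + se_2^2}$ -- the strata are disjoint individuals, so
they are treated as independent. The two ratios do share a denominator, so
this SE slightly double-counts denominator noise; under the null the
numerators dominate and the test is correctly calibrated (verified by
simulation at nominal 5%).

**The denominator choice.** In the published analysis the denominator was
the association between the participants' *own* genotype and their *own*
cigarettes/day among smokers -- a quantity only a real biobank provides. In
the simulation pipeline the denominator regresses maternal cigarettes/day
on the *offspring* dosage among smoking mothers. This is deliberate:
numerator and denominator then attenuate by the same transmission factor
(≈0.5), so the Wald ratio is consistent for the per-cigarette causal
effect. Using an unattenuated (own-genotype) denominator halves the
estimand; since the package's simulations are used to verify parameter
recovery, the attenuation-matched denominator is the right default.

**Proxy attenuation.** Because the offspring genotype is a noisy proxy,
it explains only $\mathrm{corr}(G_m, G_o)^2 = 1/4$ of the exposure variance
that the maternal genotype explains. `proxyAttenuation()` measures this
directly by simulation; it is the package's headline reproduction of the
design's known ~25% power penalty.

## Numerical and design choices

* **Month-of-birth encoding.** $s(m) = \cos(\pi(m - 6.5)/3)$: period six
  months, peaks in June/July and December/January, troughs in
  spring/autumn. The source describes only "a cosine with peaks in summer
  and winter"; this phase/amplitude convention satisfies that description
  and is tested for its symmetry $s(m) = s(m+6)$.
* **Clumping ties.** Greedy p-value-ordered clumping breaks p ties by
  (chromosome, position, SNP id), making results invariant to input row
  order. r² is computed on the analysis panel's dosages and is therefore
  panel-dependent; the window is symmetric and inclusive
  ($|pos_i - pos_j| \le$ window). Zero-variance panel columns are skipped
  with a warning; a SNP missing from the panel is an error.
* **Harmonization.** Counted-allele = effect-allele keeps the weight,
  counted = other flips its sign, A/T and C/G palindromes and mismatches
  are dropped with a report (no strand inference is attempted).
* **Missing dosages** in scoring are mean-imputed per column
  (2 × allele frequency in expectation).
* **Separation and rank deficiency.** Logistic fits flag non-convergence
  and fitted probabilities at 0/1 in the result table rather than failing;
  collinear designs raise an error naming the aliased terms.
* **CIs** are Wald-type, 95%, two-sided throughout, matching the
  reporting style of the published tables; no profile likelihood, no
  bootstrap.
* **Categorical country** is dummy-coded against England (the modal
  category); Townsend is z-scored; other continuous predictors enter
  untransformed.
* **Two-level outcome.** "Uses both hands equally" responses are assumed
  excluded upstream; `fitLogistic()` enforces a two-level outcome.
* **Determinism.** Every stochastic routine is driven by an explicit seed;
  `runPipeline()` requires one in its config and emits a manifest (seed,
  version, row counts per filter) sufficient to reproduce a run exactly.
  Replicate seeds in the power module are drawn once from the master seed.

## The power and calibration harness

`runPowerScenario()` converts each causal odds ratio per SD of
cigarettes/day into a per-cigarette log-odds via the scenario's exposure
SD, simulates cohorts, runs the full stratified pipeline, and reports
rejection rate, mean estimate, bias, CI coverage and the Monte-Carlo SE
$\sqrt{p(1-p)/R}$. "Well powered" is operationalized as power ≥ 0.80 where
a threshold is needed. Replicate counts, effect grids and alpha are free
parameters (the original study's exact simulation grid is not public);
desk-scale defaults (hundreds of replicates at tens of thousands of pairs)
are chosen to keep a full calibration run in minutes. For calibration
experiments at reduced n, the instrument weight is scaled up (e.g. 3.5
cigarettes/day per allele at n = 20,000) so the denominator F statistic
stays in the strong-instrument regime (~100) that the full-scale design
occupies; calibration conclusions are about the estimator, not about
power at biobank scale, which is config-driven.

`colliderDemo()` packages the two documented bias mechanisms as
reproducible contrasts: stratifying on smoking status (a collider between
genotype and confounders of initiation) induces an instrument--confounder
association *within* strata that is absent marginally; adjusting for
birthweight (a collider between smoking and confounders of birthweight)
moves the smoking--handedness odds ratio away from its crude value, in the
"stronger association" direction.

## Known limitations

The pleiotropy correction assumes equal pleiotropic effects across strata
and no genotype--initiation path; the collider demonstrations show exactly
how it fails otherwise, and the correction is not applied automatically in
those worlds. The delta-method SE is first-order and shared-denominator
correlation is ignored (conservative near the null). Logistic
non-collapsibility makes the per-cigarette marginal estimand differ
slightly from the conditional coefficient at large effect sizes; at the
effect magnitudes studied here the difference is well inside Monte-Carlo
noise. The generator draws covariates independently of genotype, so
negative-control regressions are null by construction -- they validate the
machinery, not the exchangeability of any real cohort.
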