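---
title: "Genetic risk scores and gene-diet interactions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores and gene-diet interactions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsdiet)
```

## The analysis this package implements

`grsdiet` implements a candidate-gene nutrigenetic analysis of the kind
used in small observational cohorts: two unweighted genetic risk scores
(GRS) are built from SNP panels — five vitamin D pathway variants
(*DHCR7*, *CYP2R1*, *CYP24A1*, *GC*, *CASR*) and ten obesity/type 2
diabetes variants (*FTO*, *TCF7L2*, *MC4R*, *KCNQ1*, *CDKN2A/B*) — and
used as genetic instruments for, respectively, vitamin D status and
metabolic disease susceptibility. Each score is the per-subject count of
risk alleles,

$$\mathrm{GRS}_i = \sum_{j \in \text{panel}} d_{ij}, \qquad
  d_{ij} \in \{0, 1, 2\},$$

with no effect-size weights (a weights hook exists in principle, but the
unweighted count is the analysis as specified). Scores are dichotomized at
an integer threshold derived from the sample median into low/high genetic
risk groups, and three families of models are fit:

* **Association**: outcome ~ GRS group + covariates (OLS with intercept);
* **Interaction**: outcome ~ GRS group + diet + GRS group x diet +
  covariates, reporting the product term;
* **Stratified contrasts**: within tertiles of dietary intake, the
  adjusted low-vs-high group difference, to localize a significant
  interaction.

All tests are two-sided; p-values are nominal, with a Bonferroni column
emitted alongside for the model grid.

## Genotype handling

Raw calls are oriented to **risk-allele dosages** explicitly, never by
minor-allele status: minor alleles are population-dependent (for *DHCR7*
rs12785878 the minor allele differs between East/South Asian and European
populations), so every panel entry declares its risk and other allele and
`orient_call()` counts risk alleles, flipping coded dosages (`2 - d`) when
they were coded on the non-risk allele. The shipped panel marks its
risk-allele assignments as *placeholders*: they follow the conventional
GWAS effect alleles, but because the package cannot verify them against
any particular genotyping report, `run_pipeline()` refuses to run until
the caller passes `accept_panel = TRUE`.

Each SNP is screened for Hardy-Weinberg equilibrium with a Pearson
goodness-of-fit chi-square: the allele frequency is estimated from the
genotype counts, expected counts are $np^2, 2npq, nq^2$, and the statistic
is referred to a chi-square with **1 degree of freedom** (one parameter
estimated), without continuity correction. Monomorphic SNPs return
chi-square 0 and p 1 by convention; exact tests are out of scope. The
1-df chi-square is slightly conservative when expected heterozygote
counts are small, so the calibration checks in the test suite use
MAF >= 0.2 at n = 110.

Missing calls propagate: a subject missing any call in a panel is dropped
from that panel's score (complete-case), mirroring the exclusion of
incompletely genotyped subjects from the analyzed cohort; per-SNP mean
imputation is available as an option (`impute = "mean"`).

## Derived phenotypes and transforms

* BMI = weight / height^2 (kg/m^2).
* LDL-c by Friedewald: TC − HDL-c − TG/5, refused when TG >= 400 mg/dL
  (outside the formula's validity domain).
* Vitamin D status from serum 25(OH)D by the Institute of Medicine bands:
  sufficient >= 20 ng/mL, insufficient [12, 20), deficient < 12. The
  insufficiency band is conventionally printed as "12–19", which leaves
  (19, 20) unassigned; we resolve it half-open at 20 so the three classes
  partition the positive line.
* Percent energy from a macronutrient = 100 x kcal_per_g x grams /
  energy, with Atwater factors 4/4/9 kcal/g for
  carbohydrate/protein/fat (configurable; the factor is a convention,
  not a measurement).

Every continuous analysis variable passes through a **normality-gated
log transform**: Shapiro-Wilk at alpha = 0.05, and variables that reject
are analyzed as their base-10 logarithm. Base 10 is deliberate: published
log-scale group means for 25(OH)D near 1.2–1.3 against raw means near
16–19 ng/mL, and log BFP means near 1.5–1.6 against raw BFP of 34–40%,
are only consistent with log10. The transform applied to each variable is
recorded in the run manifest, and descriptive tables always report
raw-scale means +- SD even when the test ran on the log scale.

## Model conventions

**Adjustment sets.** The default adjustment is age, BMI, and location
(urban/rural); interaction models add total energy intake because the
dietary exposures are energy-bearing grams. "Adjust wherever
appropriate" is operationalized as: BMI leaves the adjustment set
whenever the outcome is itself an adiposity measure (BMI, WC, BFP), so no
outcome is adjusted for itself or a near-alias. The exact adjustment set
of every fit is recorded in its output row and in the manifest, so an
alternative reading is a config change, not a code change.

**Median split.** The sample median of an integer score can be
fractional; the threshold is the *floored* median, and the two boundary
conventions seen in published splits are both first-class: `le_low`
(score <= t is low risk; the vitamin D panel default, matching a
"<=2 vs >2" split) and `lt_low` (score < t is low; the metabolic panel
default, matching "<4 vs >=4"). Thresholds are computed on the analysis
sample and logged; whether a published median predates exclusions is
unknowable from printed results, so the manifest makes our choice
explicit.

**Interaction term.** The GRS enters interaction models as the binary
median-split group (matching how stratified results are presented); a
continuous-score variant is available by passing the score column. The
diet variable enters on its transform scale as flagged — at study scale
the Shapiro gate usually log-transforms intake grams, so the product-term
coefficient is per log10-gram; a raw-scale fit is obtained by passing the
untransformed column.

**ANOVA from summaries.** Published descriptive tables print per-group
(n, mean, SD); `anova_from_summary()` rebuilds the classical one-way
decomposition from exactly those numbers (SSB from group means around the
grand mean, SSW = sum (n-1) sd^2) and is algebraically identical to
`anova_oneway()` on any raw data having those summaries — the identity is
property-tested, and lets the package check its descriptive tables
against published ones without raw data.

**Degenerate inputs.** Zero-variance predictors and aliased designs stop
with a "singular design" error naming the predictor; tertile x group
cells with n < 2 are flagged and their p suppressed rather than reported;
a constant score vector yields a single risk group with a warning; a
constant variable collapses tertiles to T1 with a warning.

## The synthetic cohort

Because the motivating study's individual-level data are not deposited,
the generator is the package's test bed. It emulates:

* 15 biallelic SNPs drawn independently under HWE,
  dosage ~ Binomial(2, MAF), default MAF 0.3 for every SNP (cohort
  allele frequencies are not published; configurable per SNP);
* age truncated-normal (40.46, 9.38) on [25, 60]; 51% urban;
  carbohydrate truncated-normal with mean 233.08 g/d, SD 71.34, range
  [121, 436]; energy centred on 1776 kcal/d;
* planted linear effects: BMI rises 0.55 kg/m^2 per metabolic risk
  allele, log10 25(OH)D falls 0.024 per metabolic risk allele, and log10
  BFP carries an interaction of 8e-4 per gram of carbohydrate (centered)
  for subjects in the high vitamin D-GRS group. The defaults were chosen
  once to roughly reproduce the published low/high group-mean gaps (BMI
  24.25 vs 26.10; log 25(OH)D 1.28 vs 1.20; top-tertile log BFP 1.53 vs
  1.60) and are labelled as such — true coefficients are not printed
  anywhere, only group means.

Two generator details matter for interpretation. First, truncation
shifts a normal's mean (the [121, 436] carbohydrate window is asymmetric
about 233), so the generator solves for the pre-truncation location that
gives the *truncated* distribution the stated mean — published means are
observed sample moments, i.e. post-truncation. The truncated SD is
correspondingly a few percent below the nominal SD; only the mean is
matched exactly. Second, 25(OH)D and BFP are generated on the log10
scale and stored back-transformed, so their raw columns are lognormal
and the Shapiro gate rediscovers the log scale the analysis expects.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (draws are independent), population stratification, correlation
between diet and covariates beyond what the planted effects induce, FFQ
measurement error, or assay noise. Passing calibration and recovery
tests therefore demonstrates that the *statistical machinery* is correct
and unbiased under the assumed data-generating process — not that the
published cohort's estimates are reproduced.

## Simulation studies shipped with the package

The test suite and analysis scripts run, at sizes chosen to keep the
whole suite around a minute:

* **Type-I error**: 2000 null SNPs (n = 110, MAF 0.3) for the HWE test
  and 1000 null cohorts (n = 110) for the interaction term, both
  asserted to reject in [0.03, 0.07] at alpha 0.05;
* **Parameter recovery**: 500 replicates at n = 5000, asserting 95% CI
  coverage in [0.92, 0.97] and mean bias within Monte-Carlo error of
  zero for all three planted coefficients;
* **Power mapping** (`analysis/03_calibration.R`): rejection rates over
  a {0, 8e-4, 2e-3} x {110, 500, 1000} grid, 200 replicates per cell.
  At the study size the default-size interaction is detected in roughly
  80% of replicates, and null cells sit at the nominal 5%; the study
  design itself reports no power calculation, so these numbers are
  reported, not asserted.

## Limitations

Unweighted scores weight a weak variant equally with a strong one; the
median split discards within-group dosage information; complete-case
panel scoring can bias if missingness tracks genotype; nominal p-values
over an 88-model interaction grid invite multiplicity concerns (the
Bonferroni column is emitted precisely so readers can see how fragile a
single nominal hit is); and the pipeline's Shapiro gate makes the
analysis scale data-dependent, which is faithful to the specified
procedure but means two cohorts can be analyzed on different scales.
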