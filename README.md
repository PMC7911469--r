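# grsdiet

Genetic risk scores and gene–diet interaction analysis for small
nutrigenetic cohort studies.

Candidate-gene nutrigenetics asks whether the association between a
genetic predisposition and a clinical trait is modified by diet. This
package implements that analysis end to end for two unweighted genetic
risk scores (GRS) — a five-SNP vitamin D pathway score (*DHCR7*,
*CYP2R1*, *CYP24A1*, *GC*, *CASR*) and a ten-SNP metabolic disease score
(*FTO*, *TCF7L2*, *MC4R*, *KCNQ1*, *CDKN2A/B*) — against anthropometric
and biochemical outcomes in a cohort of around a hundred subjects. It is
aimed at epidemiologists and students who want the whole chain —
genotype orientation, Hardy–Weinberg screening, score construction,
transformation rules, adjusted models, stratified follow-up — as tested,
reproducible code rather than a statistics-package click path.

The core quantities:

* **GRS**: `GRS_i = Σ_j d_ij`, the count of risk alleles (`d ∈ {0,1,2}`
  per SNP) over a panel; dichotomized at the floored sample median into
  low/high risk groups (`≤t` low for the vitamin D panel, `<t` low for
  the metabolic panel).
* **HWE screen**: Pearson goodness-of-fit chi-square on genotype counts
  with allele frequency estimated from the sample, 1 df.
* **Association**: `outcome ~ GRS group + age + BMI + location` (OLS;
  BMI leaves the adjustment set for adiposity outcomes).
* **Interaction**: `outcome ~ GRS group × diet + covariates + energy`,
  reporting the product term; significant interactions are followed up
  within tertiles of intake.
* Continuous variables are log10-transformed when Shapiro–Wilk rejects
  normality; every transform and adjustment set is recorded in a run
  manifest.

A seeded synthetic-cohort generator (`simulate_cohort()`) reproduces the
assumed data-generating process — SNPs in HWE, truncated-normal diet
matched to published cohort descriptives, planted genetic main effects
and a GRS×carbohydrate interaction on log body fat — so calibration,
power and parameter-recovery studies run without access to any real
data.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated cohort. Step 1 writes the inputs, step 2 runs the pipeline:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pipeline.R
```

```
HWE:  13 of 15 SNPs in equilibrium at alpha 0.05
GRS splits: vitamin D <=3 low (le_low); metabolic <6 low (lt_low)

Metabolic-GRS associations (focal = high vs low group):
 outcome estimate     se       p log_outcome n_used
     bmi    0.770 0.8454 0.36470       FALSE    110
    vitd   -0.123 0.0373 0.00134        TRUE    110

Vitamin D-GRS x carbohydrate on BFP:
               term estimate    se      p log_outcome
 grs_grouphigh:carb    0.318 0.152 0.0384        TRUE
```

Reading it: at n = 110 the high metabolic-risk group shows 0.123 lower
log10 25(OH)D (p = 0.0013) — the planted effect — while the same-size
planted BMI effect is not significant at this sample size (p = 0.36),
a deliberate illustration of how underpowered single associations are
at study scale. The vitamin D-GRS × carbohydrate product term on log10
BFP is 0.318 per log10-gram (carbohydrate was log-transformed by the
normality gate; p = 0.038), and the pipeline writes the tertile-
stratified follow-up table `stratified_vitamin_d_carb_bfp.tsv` showing
where in the intake range the group contrast concentrates. The full
bundle (HWE report, GRS table, descriptives stratified by vitamin D
status with ANOVA p per row, all 22 association and 88 interaction
fits with Bonferroni columns, manifest) lands in `results/bundle/`.

Steps 3 and 4 map the interaction test's type-I error and power over a
grid of effect sizes and sample sizes, and verify that the planted
coefficients are recovered with nominal 95% CI coverage at n = 5000.

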