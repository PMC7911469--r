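#' Seeded synthetic cohorts with planted genetic and gene-diet effects
#'
#' Generates genotype + phenotype tables with the statistical structure the
#' analysis assumes: 15 biallelic SNPs drawn under Hardy-Weinberg
#' equilibrium, diet and covariate distributions matched to the cohort's
#' published descriptives, a metabolic-score main effect on BMI and on log10
#' 25(OH)D, and a configurable vitamin D-GRS-by-carbohydrate interaction on
#' log10 body fat percentage. Every planted coefficient is returned in a
#' truth record so recovery and calibration studies can close the loop.
#'
#' @name synthetic_cohort
NULL

# Truncated normal via inverse-CDF; exact and vectorized. The location is
# adjusted so the TRUNCATED distribution has the requested mean (published
# cohort means are observed sample moments, i.e. post-truncation).
.tn_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

.tn_location <- function(target, sd, lo, hi) {
  stats::uniroot(function(m) .tn_mean(m, sd, lo, hi) - target,
                 interval = c(lo - 5 * sd, hi + 5 * sd),
                 tol = 1e-10)$root
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  mu <- .tn_location(mean, sd, lower, upper)
  lo <- stats::pnorm(lower, mu, sd)
  hi <- stats::pnorm(upper, mu, sd)
  stats::qnorm(stats::runif(n, lo, hi), mu, sd)
}

#' Simulation parameters
#'
#' Defaults emulate the study conditions: n = 110 women aged 25-60 (mean
#' 40.46, SD 9.38), 51% urban, carbohydrate intake truncated-normal with
#' mean 233.08 g/d, SD 71.34, range [121, 436], energy intake centred on
#' 1776 kcal/d. Planted effect sizes default to values that roughly
#' reproduce the published low/high risk-group gaps (BMI 24.25 vs 26.10,
#' log10 25(OH)D 1.28 vs 1.20, top-tertile log10 BFP 1.53 vs 1.60); they
#' are per-risk-allele (main effects) or per-gram-of-carbohydrate
#' (interaction) linear coefficients.
#'
#' @param n Number of subjects.
#' @param maf Minor (here: risk) allele frequencies, one per panel SNP
#'   (named by rsID) or a single value recycled; all in (0, 1).
#' @param beta_metabolic_on_bmi BMI increase (kg/m^2) per metabolic risk
#'   allele.
#' @param beta_metabolic_on_log_vitd Decrease in log10 25(OH)D per
#'   metabolic risk allele (entered with a minus sign).
#' @param beta_interaction Increase in log10 BFP per gram of daily
#'   carbohydrate for subjects in the high vitamin D-GRS group (centered
#'   carbohydrate enters the product).
#' @param beta_vitd_group_on_log_bfp Main effect of the high vitamin D-GRS
#'   group on log10 BFP at the mean carbohydrate intake.
#' @param carb_mean,carb_sd,carb_range Carbohydrate intake distribution
#'   (g/d, truncated normal).
#' @param energy_mean,energy_sd,energy_range Energy intake (kcal/d).
#' @param age_mean,age_sd,age_range Age (years, truncated normal).
#' @param urban_fraction Probability of urban residence.
#' @param bmi_sd,logvitd_sd,logbfp_sd Residual noise SDs of the generated
#'   outcomes.
#' @param panel A `snp_panel`; defaults to the shipped panel.
#' @param seed Integer seed; every draw in [simulate_cohort()] descends
#'   from it.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n = 110,
                       maf = 0.3,
                       beta_metabolic_on_bmi = 0.55,
                       beta_metabolic_on_log_vitd = 0.024,
                       beta_interaction = 8e-4,
                       beta_vitd_group_on_log_bfp = 0,
                       carb_mean = 233.08, carb_sd = 71.34,
                       carb_range = c(121, 436),
                       energy_mean = 1776, energy_sd = 600,
                       energy_range = c(800, 4200),
                       age_mean = 40.46, age_sd = 9.38,
                       age_range = c(25, 60),
                       urban_fraction = 0.51,
                       bmi_sd = 4.0, logvitd_sd = 0.20, logbfp_sd = 0.08,
                       panel = load_panel(),
                       seed = 1L) {
  stopifnot(n >= 2, carb_sd > 0, energy_sd > 0, age_sd > 0,
            bmi_sd > 0, logvitd_sd > 0, logbfp_sd > 0,
            carb_range[1] < carb_range[2],
            energy_range[1] < energy_range[2],
            age_range[1] < age_range[2],
            urban_fraction > 0, urban_fraction < 1)
  if (length(maf) == 1) maf <- stats::setNames(rep(maf, nrow(panel)),
                                               panel$rsid)
  if (length(maf) != nrow(panel))
    stop("need one MAF per panel SNP (", nrow(panel), ")")
  if (is.null(names(maf))) names(maf) <- panel$rsid
  if (any(maf <= 0 | maf >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")

  # Baselines anchor the generated means at the published cohort means
  # given the expected risk-allele load implied by the MAFs.
  e_met <- 2 * sum(maf[panel$rsid[panel$panel == "metabolic"]])
  structure(list(
    n = n, maf = maf, panel = panel,
    beta_metabolic_on_bmi = beta_metabolic_on_bmi,
    beta_metabolic_on_log_vitd = beta_metabolic_on_log_vitd,
    beta_interaction = beta_interaction,
    beta_vitd_group_on_log_bfp = beta_vitd_group_on_log_bfp,
    bmi_baseline = 25.2 - beta_metabolic_on_bmi * e_met,
    logvitd_baseline = 1.25 + beta_metabolic_on_log_vitd * e_met,
    logbfp_baseline = 1.55,
    carb_mean = carb_mean, carb_sd = carb_sd, carb_range = carb_range,
    energy_mean = energy_mean, energy_sd = energy_sd,
    energy_range = energy_range,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    urban_fraction = urban_fraction,
    bmi_sd = bmi_sd, logvitd_sd = logvitd_sd, logbfp_sd = logbfp_sd,
    seed = as.integer(seed)), class = "sim_params")
}

# Unseeded genotype draw: dosage_j ~ Binomial(2, maf_j) iid over subjects.
.gen_genotypes <- function(params) {
  n <- params$n
  panel <- params$panel
  dosage <- vapply(panel$rsid,
                   function(rs) stats::rbinom(n, 2L, params$maf[[rs]]),
                   integer(n))
  dimnames(dosage) <- list(NULL, panel$rsid)
  structure(list(subject_id = sprintf("S%04d", seq_len(n)),
                 panel = panel,
                 dosage = dosage,
                 missing = matrix(FALSE, n, nrow(panel),
                                  dimnames = list(NULL, panel$rsid))),
            class = "genotype_matrix")
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' @param params A `sim_params`.
#' @param seed Seed; defaults to `params$seed`.
#' @return A `genotype_matrix` of risk-allele dosages.
#' @export
simulate_genotypes <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  .gen_genotypes(params)
}

#' Simulate a full cohort with planted effects
#'
#' Genotypes are drawn under HWE; the metabolic GRS raises BMI and lowers
#' log10 25(OH)D linearly per risk allele; log10 BFP carries the planted
#' vitamin D-GRS-group-by-centered-carbohydrate interaction. 25(OH)D and
#' BFP are stored back-transformed (so the raw columns are lognormal, and
#' the normality-gated transform step rediscovers the log scale). The
#' vitamin D risk group used in generation is the package's own median
#' split of the vitamin D GRS, recorded in the truth record.
#'
#' @param params A `sim_params`.
#' @param seed Seed; defaults to `params$seed`.
#' @return List with `cohort` (data frame in the analysis header contract),
#'   `genotypes` (a `genotype_matrix`) and `truth` (planted coefficients,
#'   the generation-time risk groups and split threshold).
#' @export
simulate_cohort <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  n <- params$n
  gm <- .gen_genotypes(params)

  met_score <- compute_grs(gm, "metabolic")$score
  vit <- grs_groups(gm, "vitamin_d")
  v_high <- as.integer(vit$group == "high")

  age <- .rtruncnorm(n, params$age_mean, params$age_sd,
                     params$age_range[1], params$age_range[2])
  location <- ifelse(stats::runif(n) < params$urban_fraction,
                     "urban", "rural")
  carb <- .rtruncnorm(n, params$carb_mean, params$carb_sd,
                      params$carb_range[1], params$carb_range[2])
  energy <- .rtruncnorm(n, params$energy_mean, params$energy_sd,
                        params$energy_range[1], params$energy_range[2])
  protein <- .rtruncnorm(n, 77, 37, 20, 250)
  fat <- .rtruncnorm(n, 59, 33, 10, 220)
  fiber <- .rtruncnorm(n, 8.8, 4.3, 1, 30)
  height <- .rtruncnorm(n, 1.53, 0.06, 1.35, 1.75)

  bmi_val <- params$bmi_baseline +
    params$beta_metabolic_on_bmi * met_score +
    stats::rnorm(n, 0, params$bmi_sd)
  weight <- bmi_val * height^2
  wc <- 30 + 2.1 * bmi_val + stats::rnorm(n, 0, 5)

  log_vitd <- params$logvitd_baseline -
    params$beta_metabolic_on_log_vitd * met_score +
    stats::rnorm(n, 0, params$logvitd_sd)
  log_bfp <- params$logbfp_baseline +
    params$beta_vitd_group_on_log_bfp * v_high +
    params$beta_interaction * v_high * (carb - params$carb_mean) +
    stats::rnorm(n, 0, params$logbfp_sd)

  glucose <- .rtruncnorm(n, 92.5, 18, 60, 250)
  hba1c <- .rtruncnorm(n, 640, 550, 100, 4000)
  insulin <- .rtruncnorm(n, 31000, 24000, 5000, 200000)
  tc <- .rtruncnorm(n, 208, 44, 100, 390)
  hdl <- .rtruncnorm(n, 59, 10.5, 30, 95)
  tg <- .rtruncnorm(n, 98, 43, 30, 399)

  cohort <- data.frame(
    subject_id = gm$subject_id,
    age = age, location = location,
    weight = weight, height = height, wc = wc,
    bfp = 10^log_bfp, vitd = 10^log_vitd,
    glucose = glucose, hba1c = hba1c, insulin = insulin,
    tc = tc, hdl = hdl, tg = tg,
    energy = energy, carb = carb, protein = protein,
    fat = fat, fiber = fiber,
    stringsAsFactors = FALSE)

  truth <- list(
    seed = seed,
    beta_metabolic_on_bmi = params$beta_metabolic_on_bmi,
    beta_metabolic_on_log_vitd = params$beta_metabolic_on_log_vitd,
    beta_interaction = params$beta_interaction,
    beta_vitd_group_on_log_bfp = params$beta_vitd_group_on_log_bfp,
    carb_mean = params$carb_mean,
    vitd_threshold = attr(vit, "threshold"),
    vitd_group = vit$group,
    metabolic_score = met_score)

  list(cohort = cohort, genotypes = gm, truth = truth)
}

#' Refit the planted effects from a simulated cohort
#'
#' Fits the generating designs back to the data (BMI and log10 25(OH)D on
#' the metabolic score; log10 BFP on vitamin D group x carbohydrate) and
#' reports each planted coefficient with its estimate, SE and 95% CI.
#'
#' @param sim Result of [simulate_cohort()].
#' @return Data frame: effect, truth, estimate, se, ci_lo, ci_hi, covered.
#' @export
recover_effects <- function(sim) {
  co <- sim$cohort
  d <- data.frame(
    bmi = bmi(co$weight, co$height),
    log_vitd = log10(co$vitd),
    log_bfp = log10(co$bfp),
    met = sim$truth$metabolic_score,
    vgroup = factor(sim$truth$vitd_group, levels = c("low", "high")),
    carb = co$carb)

  one <- function(name, truth, fit, term) {
    ct <- summary(fit)$coefficients
    est <- ct[term, 1]; se <- ct[term, 2]
    ci <- est + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
    data.frame(effect = name, truth = truth, estimate = est, se = se,
               ci_lo = ci[1], ci_hi = ci[2],
               covered = truth >= ci[1] & truth <= ci[2],
               stringsAsFactors = FALSE)
  }
  rbind(
    one("beta_metabolic_on_bmi", sim$truth$beta_metabolic_on_bmi,
        stats::lm(bmi ~ met, d), "met"),
    one("beta_metabolic_on_log_vitd", -sim$truth$beta_metabolic_on_log_vitd,
        stats::lm(log_vitd ~ met, d), "met"),
    one("beta_interaction", sim$truth$beta_interaction,
        stats::lm(log_bfp ~ vgroup * carb, d), "vgrouphigh:carb"))
}

#' Type-I error / power calibration of the interaction test
#'
#' For each grid row (n, beta_interaction), simulates `n_reps` cohorts,
#' fits the interaction model log10 BFP ~ group * carbohydrate adjusted for
#' age, location and energy, and reports the empirical rejection rate of
#' the interaction term with its Monte-Carlo standard error.
#'
#' @param grid Data frame with columns `n` and `beta_interaction`.
#' @param n_reps Replicates per cell (>= 100).
#' @param alpha Nominal significance level.
#' @param seed Base seed; replicate r of cell i uses seed + 1000*i + r.
#' @param ... Further arguments passed to [sim_params()].
#' @return `grid` with columns `rejection_rate` and `mc_se` appended.
#' @export
run_calibration <- function(grid, n_reps = 200, alpha = 0.05, seed = 1L,
                            ...) {
  stopifnot(n_reps >= 100, all(c("n", "beta_interaction") %in% names(grid)))
  grid$rejection_rate <- NA_real_
  grid$mc_se <- NA_real_
  for (i in seq_len(nrow(grid))) {
    params <- sim_params(n = grid$n[i],
                         beta_interaction = grid$beta_interaction[i], ...)
    rej <- vapply(seq_len(n_reps), function(r) {
      sim <- simulate_cohort(params, seed = seed + 1000L * i + r)
      p <- interaction_pvalue(sim)
      p < alpha
    }, logical(1))
    grid$rejection_rate[i] <- mean(rej)
    grid$mc_se[i] <- sqrt(mean(rej) * (1 - mean(rej)) / n_reps)
  }
  grid
}

#' Interaction-term p-value for a simulated cohort
#'
#' Convenience wrapper running the analysis-side interaction model (log10
#' BFP on vitamin D risk group x carbohydrate grams, adjusted for age,
#' location and energy) on one simulated cohort.
#'
#' @param sim Result of [simulate_cohort()].
#' @return The two-sided p-value of the interaction coefficient.
#' @export
interaction_pvalue <- function(sim) {
  co <- sim$cohort
  d <- data.frame(log_bfp = log10(co$bfp),
                  grs_group = factor(sim$truth$vitd_group,
                                     levels = c("low", "high")),
                  carb = co$carb, age = co$age,
                  location = co$location, energy = co$energy)
  fit <- fit_interaction(d, "log_bfp", "carb",
                         adjustment = c("age", "location", "energy"),
                         transformed = TRUE)
  focal_row(fit)$p
}

# Map risk-allele dosages back to two-character allele-pair calls.
.dosage_to_calls <- function(gm) {
  panel <- gm$panel
  calls <- matrix("", nrow(gm$dosage), ncol(gm$dosage),
                  dimnames = dimnames(gm$dosage))
  for (j in seq_len(nrow(panel))) {
    r <- panel$risk_allele[j]; o <- panel$other_allele[j]
    map <- c(paste0(o, o), paste0(r, o), paste0(r, r))
    d <- gm$dosage[, j]
    calls[, j] <- ifelse(is.na(d), "", map[d + 1L])
  }
  calls
}

#' Write a simulated cohort to analysis-ready input files
#'
#' Emits `<prefix>_genotypes.csv` (allele-pair calls), `<prefix>_cohort.csv`
#' (phenotype/diet table in the validator's header contract) and
#' `<prefix>_truth.json` (planted coefficients).
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_simulated_inputs <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno_path <- file.path(dir, paste0(prefix, "_genotypes.csv"))
  cohort_path <- file.path(dir, paste0(prefix, "_cohort.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))

  calls <- .dosage_to_calls(sim$genotypes)
  geno_df <- data.frame(subject_id = sim$genotypes$subject_id, calls,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(geno_df, geno_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$cohort, cohort_path, row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$vitd_group <- NULL
  truth$metabolic_score <- NULL
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(genotypes = geno_path, cohort = cohort_path,
              truth = truth_path))
}
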