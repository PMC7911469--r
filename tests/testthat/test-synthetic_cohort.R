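test_that("sim_params validates its inputs", {
  expect_error(sim_params(maf = 0), "strictly in")
  expect_error(sim_params(maf = 1), "strictly in")
  expect_error(sim_params(maf = rep(0.3, 7)), "one MAF per panel SNP")
  p <- sim_params(maf = 1e-6, n = 100, seed = 3)
  gm <- simulate_genotypes(p)
  expect_true(all(gm$dosage == 0))
})

test_that("genotype draws match binomial expectations and respect the seed", {
  p <- sim_params(n = 10000, maf = 0.5, seed = 12)
  gm <- simulate_genotypes(p)
  # mean dosage 2*maf = 1, SE = sqrt(2*0.5*0.5/10000) per SNP
  se <- sqrt(0.5 / 10000)
  expect_true(all(abs(colMeans(gm$dosage) - 1) < 3 * se * sqrt(15) + 3 * se))
  expect_lt(abs(mean(gm$dosage) - 1), 3 * se / sqrt(15))
  # bit-identical under the same seed, different under another
  gm2 <- simulate_genotypes(p)
  expect_identical(gm$dosage, gm2$dosage)
  gm3 <- simulate_genotypes(p, seed = 13)
  expect_false(identical(gm$dosage, gm3$dosage))
})

test_that("simulate_cohort is deterministic and passes the validator", {
  p <- sim_params(seed = 42)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  v <- validate_cohort(a$cohort)
  expect_true(v$ok)
  expect_length(v$errors, 0)
  expect_equal(nrow(a$cohort), 110)
  # truth record carries every planted coefficient
  expect_named(a$truth, c("seed", "beta_metabolic_on_bmi",
                          "beta_metabolic_on_log_vitd", "beta_interaction",
                          "beta_vitd_group_on_log_bfp", "carb_mean",
                          "vitd_threshold", "vitd_group",
                          "metabolic_score"))
})

test_that("default cohorts match the target diet distribution", {
  p <- sim_params(n = 5000, seed = 77)
  sim <- simulate_cohort(p)
  carb <- sim$cohort$carb
  # truncation slightly shrinks the SD; 3*SE band around the target mean
  expect_lt(abs(mean(carb) - 233.08), 3 * 71.34 / sqrt(5000))
  expect_gte(min(carb), 121)
  expect_lte(max(carb), 436)
  expect_true(all(sim$cohort$age >= 25 & sim$cohort$age <= 60))
  frac_urban <- mean(sim$cohort$location == "urban")
  expect_lt(abs(frac_urban - 0.51), 3 * sqrt(0.51 * 0.49 / 5000))
})

test_that("planted metabolic effects move group means the right way", {
  p <- sim_params(n = 5000, seed = 101)
  sim <- simulate_cohort(p)
  co <- derive_phenotypes(sim$cohort)
  m <- sim$truth$metabolic_score
  thr <- median_threshold(m)
  high <- m >= thr
  expect_gt(mean(co$bmi[high]), mean(co$bmi[!high]))
  expect_lt(mean(log10(co$vitd[high])), mean(log10(co$vitd[!high])))
})

test_that("null cohorts give uniform association p-values", {
  p0 <- sim_params(beta_metabolic_on_bmi = 0,
                   beta_metabolic_on_log_vitd = 0,
                   beta_interaction = 0)
  pvals <- vapply(1:200, function(r) {
    sim <- simulate_cohort(p0, seed = 5000 + r)
    co <- sim$cohort
    d <- data.frame(bmi = bmi(co$weight, co$height),
                    met = sim$truth$metabolic_score)
    summary(lm(bmi ~ met, d))$coefficients["met", 4]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("recover_effects closes the simulate-score-fit loop", {
  p <- sim_params(n = 5000, seed = 303)
  rec <- recover_effects(simulate_cohort(p))
  expect_equal(nrow(rec), 3)
  # at n = 5000 every estimate sits within 4 SE of its planted value
  expect_true(all(abs(rec$estimate - rec$truth) < 4 * rec$se))
})

test_that("run_calibration rejection rates grow with effect and n", {
  grid <- data.frame(n = c(110, 110, 1000),
                     beta_interaction = c(0, 2e-3, 2e-3))
  cal <- run_calibration(grid, n_reps = 100, seed = 9)
  expect_true(all(cal$rejection_rate >= 0 & cal$rejection_rate <= 1))
  # null cell near alpha (loose 4-SE Monte Carlo band at 100 reps)
  expect_lt(cal$rejection_rate[1], 0.05 + 4 * 0.022)
  # power monotone in effect size and in n, within MC error
  tol <- 4 * sqrt(0.25 / 100)
  expect_gte(cal$rejection_rate[2], cal$rejection_rate[1] - tol)
  expect_gte(cal$rejection_rate[3], cal$rejection_rate[2] - tol)
  expect_error(run_calibration(grid, n_reps = 10), "100")
})

test_that("write_simulated_inputs round-trips through the readers", {
  sim <- simulate_cohort(sim_params(n = 40, seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_simulated_inputs(sim, dir, "rt")
  expect_true(all(file.exists(paths)))
  panel <- load_panel()
  gm <- read_genotypes(paths["genotypes"], panel)
  expect_equal(gm$dosage, sim$genotypes$dosage)
  co <- read_cohort(paths["cohort"])
  expect_equal(co$carb, sim$cohort$carb, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$beta_interaction, sim$truth$beta_interaction)
})
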