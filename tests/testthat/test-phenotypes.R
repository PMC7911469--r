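test_that("bmi and friedewald_ldl compute and guard their domains", {
  expect_equal(bmi(64, 1.6), 25)
  expect_equal(bmi(81, 1.8), 25)
  expect_error(bmi(64, 0), "positive")
  expect_error(bmi(-1, 1.6), "positive")

  expect_equal(friedewald_ldl(100, 0, 0), 100)
  expect_equal(friedewald_ldl(194, 61.2, 96.7), 113.46)
  expect_error(friedewald_ldl(200, 50, 450), "400")
  expect_error(friedewald_ldl(-1, 50, 100), "non-negative")
})

test_that("friedewald_ldl is linear: mean of LDL equals LDL of means", {
  set.seed(3)
  tc <- runif(50, 150, 250); hdl <- runif(50, 40, 80)
  tg <- runif(50, 50, 350)
  expect_equal(mean(friedewald_ldl(tc, hdl, tg)),
               friedewald_ldl(mean(tc), mean(hdl), mean(tg)))
})

test_that("classify_vitd follows the IOM bands and partitions (0, Inf)", {
  expect_equal(as.character(classify_vitd(25)), "sufficient")
  expect_equal(as.character(classify_vitd(20)), "sufficient")
  expect_equal(as.character(classify_vitd(19.5)), "insufficient")
  expect_equal(as.character(classify_vitd(12)), "insufficient")
  expect_equal(as.character(classify_vitd(11.9)), "deficient")
  expect_error(classify_vitd(0), "positive")
  # partition: every positive value gets exactly one class
  set.seed(9)
  x <- 10^runif(500, -2, 2)
  cls <- classify_vitd(x)
  expect_false(any(is.na(cls)))
  expect_equal(sum(table(cls)), 500)
})

test_that("percent_energy applies Atwater factors", {
  expect_equal(round(percent_energy(319, 1776, 4), 1), 71.8)
  expect_equal(percent_energy(0, 1776, 4), 0)
  expect_equal(percent_energy(222, 1776, 4), 50)
  expect_error(percent_energy(200, 0, 4), "positive")
})

test_that("log transform is gated by Shapiro-Wilk and uses base 10", {
  set.seed(17)
  x <- 10^rnorm(110, 1.2, 0.3)
  res <- log_transform_if_nonnormal(x)
  expect_true(res$transformed)
  expect_equal(res$values, log10(x))
  y <- rnorm(110, 50, 5)
  res <- log_transform_if_nonnormal(y)
  expect_false(res$transformed)
  expect_equal(res$values, y)
  # non-positive values cannot enter the log
  z <- c(rexp(109)^3, -1)
  expect_error(log_transform_if_nonnormal(z), "non-positive")
})

test_that("transform gate has nominal type-I error and detects lognormality", {
  set.seed(23)
  # normal inputs: flag fires at about the Shapiro-Wilk alpha
  fired <- vapply(1:2000, function(i)
    log_transform_if_nonnormal(rnorm(110, 100, 10))$transformed, logical(1))
  expect_gte(mean(fired), 0.03)
  expect_lte(mean(fired), 0.07)
  # strongly lognormal inputs (sigma = 1): flag essentially always fires
  fired <- vapply(1:500, function(i)
    log_transform_if_nonnormal(rlnorm(110, 2, 1))$transformed, logical(1))
  expect_gt(mean(fired), 0.99)
})

test_that("tertile assignment splits at sample thirds with stable ties", {
  t <- assign_tertiles(1:9)
  expect_equal(as.character(t), rep(c("T1", "T2", "T3"), each = 3))
  expect_warning(t <- assign_tertiles(rep(4, 6)), "degenerate")
  expect_true(all(t == "T1"))
  set.seed(29)
  x <- rnorm(110)
  t <- assign_tertiles(x)
  expect_lte(diff(range(table(t))), 1)
  expect_true(all(x[t == "T1"] <= min(x[t == "T3"])))
  ts <- tertile_summary(x, t)
  expect_equal(ts$n, as.vector(table(t)))
  expect_equal(ts$mean[3], mean(x[t == "T3"]))
})

test_that("validate_cohort enforces the header contract and ranges", {
  sim <- simulate_cohort(sim_params(seed = 2))
  v <- validate_cohort(sim$cohort)
  expect_true(v$ok)
  expect_length(v$errors, 0)

  bad <- sim$cohort
  bad$bfp[1] <- 130
  expect_false(validate_cohort(bad)$ok)
  bad <- sim$cohort[, setdiff(names(sim$cohort), "bfp")]
  v <- validate_cohort(bad)
  expect_false(v$ok)
  expect_match(v$errors, "bfp")
  bad <- sim$cohort
  bad$age[2] <- 70
  expect_false(validate_cohort(bad)$ok)
  # implausible macronutrient totals warn but do not error
  warn <- sim$cohort
  warn$carb <- warn$energy / 2
  v <- validate_cohort(warn)
  expect_true(v$ok)
  expect_match(v$warnings, "105")
})

test_that("derive_phenotypes adds bmi, ldl and the vitamin D class", {
  sim <- simulate_cohort(sim_params(seed = 4))
  co <- derive_phenotypes(sim$cohort)
  expect_equal(co$bmi, co$weight / co$height^2)
  expect_equal(co$ldl, co$tc - co$hdl - co$tg / 5)
  expect_equal(as.character(co$vitd_class),
               as.character(classify_vitd(co$vitd)))
})

test_that("cohort accounting subtracts exclusions from completers", {
  expect_equal(cohort_accounting(117, 6, 1), 110)
  expect_error(cohort_accounting(5, 6, 1), "exceed")
})
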