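test_that("anova_oneway matches the classical decomposition", {
  # identical group means: no between-group variance
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  r <- anova_oneway(v, g)
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    r <- anova_oneway(c(x, y), rep(c("x", "y"), c(12, 15)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(r$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }
  # cross-check against base R's decomposition
  set.seed(8)
  v <- rnorm(60); g <- sample(letters[1:3], 60, replace = TRUE)
  r <- anova_oneway(v, g)
  ref <- anova(lm(v ~ factor(g)))
  expect_equal(r$f, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("anova_from_summary is exact for data with those summaries", {
  set.seed(13)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    ns <- sample(5:20, k, replace = TRUE)
    v <- rnorm(sum(ns), mean = rep(rnorm(k, sd = 2), ns))
    g <- rep(seq_len(k), ns)
    raw <- anova_oneway(v, g)
    summ <- anova_from_summary(ns, tapply(v, g, mean), tapply(v, g, sd))
    expect_equal(summ$f, raw$f, tolerance = 1e-12)
    expect_equal(summ$p, raw$p, tolerance = 1e-12)
  }
  r <- anova_from_summary(c(10, 10), c(5, 5), c(1, 1))
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)
  expect_error(anova_from_summary(c(10, 1), c(1, 2), c(1, 1)), "n >= 2")
  expect_error(anova_from_summary(c(10, 10), c(1, 2), c(1, -1)),
               "non-negative")
})

test_that("published-style age summaries reproduce their ANOVA p-value", {
  # age by vitamin D status: (n, mean, sd) = (44, 43.8, 7.8),
  # (44, 40.0, 10.9), (22, 34.3, 10.3) -> F ~ 7.17 on (2, 107) df
  r <- anova_from_summary(c(44, 44, 22), c(43.8, 40.0, 34.3),
                          c(7.8, 10.9, 10.3))
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 107)
  expect_equal(r$f, 7.17, tolerance = 0.01)
  expect_equal(round(r$p, 3), 0.001)
})

make_model_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  data.frame(
    y = rnorm(n, 30, 5),
    grs_group = sample(c("low", "high"), n, replace = TRUE),
    age = runif(n, 25, 60),
    bmi = rnorm(n, 25, 4),
    location = sample(c("urban", "rural"), n, replace = TRUE),
    energy = rnorm(n, 1776, 500),
    carb = rnorm(n, 233, 70),
    stringsAsFactors = FALSE)
}

test_that("fit_association reports the adjusted GRS coefficient", {
  d <- make_model_data()
  d$y <- 30 + 2 * (d$grs_group == "high") + 0.1 * d$age + rnorm(120, 0, 1)
  fit <- fit_association(d, "y", adjustment = c("age", "bmi", "location"))
  row <- focal_row(fit)
  expect_equal(row$term, "grs_grouphigh")
  expect_equal(row$estimate, 2, tolerance = 3 * row$se)
  expect_equal(fit$n_used, 120)
  expect_equal(fit$adjustment_set, c("age", "bmi", "location"))
  expect_true(all(fit$terms$p >= 0 & fit$terms$p <= 1))
})

test_that("bmi leaves the adjustment set for adiposity outcomes", {
  d <- make_model_data()
  d$wc <- 30 + 2.1 * d$bmi + rnorm(120, 0, 5)
  fit <- fit_association(d, "wc", adjustment = c("age", "bmi", "location"))
  expect_false("bmi" %in% fit$adjustment_set)
  fit <- fit_association(d, "bmi", adjustment = c("age", "bmi", "location"))
  expect_false("bmi" %in% fit$adjustment_set)
  # non-adiposity outcomes keep bmi
  fit <- fit_association(d, "y", adjustment = c("age", "bmi", "location"))
  expect_true("bmi" %in% fit$adjustment_set)
  expect_error(fit_association(d, "y", adjustment = c("age", "y")),
               "own adjustment")
})

test_that("degenerate designs raise named errors", {
  d <- make_model_data()
  d$grs_group <- "low"
  expect_error(fit_association(d, "y", adjustment = "age"),
               "singular|zero variance")
  d <- make_model_data()
  d$carb <- 233
  expect_error(fit_interaction(d, "y", "carb",
                               adjustment = c("age", "location")),
               "singular|zero variance")
  expect_error(fit_association(make_model_data()[1:4, ], "y",
                               adjustment = c("age", "bmi", "location")),
               "insufficient")
})

test_that("unadjusted binary-GRS association equals the pooled t-test", {
  set.seed(19)
  for (i in 1:20) {
    d <- make_model_data(n = 60, seed = 100 + i)
    fit <- fit_association(d, "y", adjustment = character(0))
    tt <- t.test(y ~ factor(grs_group, levels = c("low", "high")),
                 data = d, var.equal = TRUE)
    expect_equal(focal_row(fit)$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("fit_interaction reports the product term on the stated design", {
  d <- make_model_data(n = 400, seed = 3)
  b_int <- 0.05
  d$y <- 20 + 1 * (d$grs_group == "high") + 0.01 * d$carb +
    b_int * (d$grs_group == "high") * d$carb + rnorm(400, 0, 2)
  fit <- fit_interaction(d, "y", "carb",
                         adjustment = c("age", "location", "energy"))
  row <- focal_row(fit)
  expect_match(row$term, ":")
  expect_equal(row$estimate, b_int, tolerance = 3 * row$se)
  expect_equal(fit$model_kind, "interaction")
  # the diet main effect is in the model, not the adjustment record
  expect_true("carb" %in% fit$terms$term)
  expect_false("carb" %in% fit$adjustment_set)
})

test_that("stratified_contrast summarizes cells and flags sparse ones", {
  d <- make_model_data(n = 150, seed = 5)
  terts <- assign_tertiles(d$carb)
  tab <- stratified_contrast(d, "y", terts,
                             adjustment = c("age", "location"))
  expect_equal(nrow(tab), 6)  # 3 tertiles x 2 groups
  expect_equal(sum(tab$n), 150)
  expect_false(any(tab$flagged))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # a tertile left with a single high-GRS subject is flagged, p suppressed
  d2 <- d
  t1_high <- which(terts == "T1" & d2$grs_group == "high")
  d2$grs_group[t1_high[-1]] <- "low"
  tab2 <- stratified_contrast(d2, "y", terts,
                              adjustment = c("age", "location"))
  expect_true(tab2$flagged[tab2$tertile == "T1" & tab2$group == "high"])
  expect_true(is.na(tab2$p[tab2$tertile == "T1"][1]))
})
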