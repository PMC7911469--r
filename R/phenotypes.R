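#' Derived phenotype variables and cohort validation
#'
#' Arithmetic derivations used throughout the analysis: body mass index,
#' Friedewald LDL cholesterol, vitamin D status classification against the
#' Institute of Medicine 25(OH)D bands, percent of energy contributed by a
#' macronutrient, Shapiro-Wilk-gated log10 transformation, and dietary
#' tertile assignment.
#'
#' @name phenotypes
NULL

#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height Height in m.
#' @return BMI in kg/m^2 (weight / height^2).
#' @export
bmi <- function(weight, height) {
  if (any(!is.na(weight) & weight <= 0) || any(!is.na(height) & height <= 0))
    stop("weight and height must be positive")
  weight / height^2
}

#' LDL cholesterol by the Friedewald formula
#'
#' LDL-c = TC - HDL-c - TG/5, all in mg/dL. Valid only for triglycerides
#' below 400 mg/dL.
#'
#' @param tc Total cholesterol (mg/dL).
#' @param hdl HDL cholesterol (mg/dL).
#' @param tg Triglycerides (mg/dL).
#' @return LDL cholesterol (mg/dL).
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(!is.na(tc) & tc < 0) || any(!is.na(hdl) & hdl < 0) ||
      any(!is.na(tg) & tg < 0))
    stop("lipid concentrations must be non-negative")
  if (any(!is.na(tg) & tg >= 400))
    stop("Friedewald formula is not valid for triglycerides >= 400 mg/dL")
  tc - hdl - tg / 5
}

#' Classify vitamin D status from serum 25(OH)D
#'
#' Institute of Medicine bands: sufficient at or above 20 ng/mL, insufficient
#' in [12, 20), deficient below 12 ng/mL. The insufficiency band is taken
#' half-open on the right so the three classes partition the positive line.
#'
#' @param vitd Serum 25(OH)D in ng/mL (positive).
#' @return Factor with levels `sufficient`, `insufficient`, `deficient`.
#' @export
classify_vitd <- function(vitd) {
  if (any(!is.na(vitd) & vitd <= 0))
    stop("25(OH)D must be positive")
  cls <- ifelse(vitd >= 20, "sufficient",
                ifelse(vitd >= 12, "insufficient", "deficient"))
  factor(cls, levels = c("sufficient", "insufficient", "deficient"))
}

#' Prevalence of each vitamin D status class
#'
#' @param vitd_class Factor from [classify_vitd()].
#' @return Named numeric vector of class percentages (summing to 100).
#' @export
vitd_prevalence <- function(vitd_class) {
  tab <- table(vitd_class)
  100 * c(tab) / sum(tab)
}

#' Percent of total energy contributed by a macronutrient
#'
#' @param grams Macronutrient intake in g/day.
#' @param energy Total energy intake in kcal/day (positive).
#' @param kcal_per_g Atwater factor: 4 kcal/g for carbohydrate and protein,
#'   9 kcal/g for fat.
#' @return Percent of total energy.
#' @export
percent_energy <- function(grams, energy, kcal_per_g = 4) {
  if (any(!is.na(energy) & energy <= 0))
    stop("energy must be positive")
  if (any(!is.na(grams) & grams < 0))
    stop("macronutrient grams must be non-negative")
  100 * kcal_per_g * grams / energy
}

#' Log10-transform a variable when Shapiro-Wilk rejects normality
#'
#' The analysis convention: every continuous variable is tested for
#' normality with the Shapiro-Wilk test; variables with p below `alpha` are
#' analyzed as their base-10 logarithm. The transform applied is recorded so
#' every downstream model can report the scale it was fit on.
#'
#' @param values Numeric vector (must be strictly positive if the transform
#'   fires).
#' @param alpha Shapiro-Wilk significance level gating the transform.
#' @return List with `values` (possibly transformed), `transformed` flag,
#'   and `shapiro_p`.
#' @export
log_transform_if_nonnormal <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 3 || stats::sd(x) == 0)
    return(list(values = values, transformed = FALSE, shapiro_p = NA_real_))
  p <- stats::shapiro.test(x)$p.value
  if (p < alpha) {
    if (any(x <= 0)) {
      bad <- which(!is.na(values) & values <= 0)
      stop("cannot log-transform non-positive values (rows ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ..." else "", ")")
    }
    list(values = log10(values), transformed = TRUE, shapiro_p = p)
  } else {
    list(values = values, transformed = FALSE, shapiro_p = p)
  }
}

#' Assign dietary intake tertiles
#'
#' Cutpoints are the 1/3 and 2/3 sample quantiles; subjects are labelled T1
#' (lowest) to T3 (highest). Ties at a cutpoint are broken by stable subject
#' order, so group sizes differ by at most one when values are distinct.
#' A constant vector collapses to a single tertile with a warning.
#'
#' @param values Numeric vector, length at least 3.
#' @return Factor with levels `T1`, `T2`, `T3` and attribute `cutpoints`.
#' @export
assign_tertiles <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values for tertiles")
  cuts <- stats::quantile(values, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  if (length(unique(values[!is.na(values)])) == 1L) {
    warning("degenerate tertile cutpoints: all values identical; ",
            "every subject assigned to T1")
    lab <- factor(rep("T1", n), levels = c("T1", "T2", "T3"))
    return(structure(lab, cutpoints = cuts))
  }
  r <- rank(values, ties.method = "first", na.last = "keep")
  m <- sum(!is.na(values))
  idx <- ceiling(3 * r / m)
  lab <- factor(c("T1", "T2", "T3")[idx], levels = c("T1", "T2", "T3"))
  structure(lab, cutpoints = cuts)
}

#' Per-tertile summary of a variable
#'
#' @param values Numeric vector summarized within tertiles.
#' @param tertiles Factor from [assign_tertiles()].
#' @return Data frame tertile, n, mean, sd.
#' @export
tertile_summary <- function(values, tertiles) {
  do.call(rbind, lapply(levels(tertiles), function(tt) {
    v <- values[!is.na(values) & tertiles == tt]
    data.frame(tertile = tt, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
}

.COHORT_REQUIRED <- c("subject_id", "age", "location", "weight", "height",
                      "wc", "bfp", "vitd", "glucose", "hba1c", "insulin",
                      "tc", "hdl", "tg", "energy", "carb", "protein",
                      "fat", "fiber")

#' Validate a cohort table
#'
#' Checks the header contract, age bounds, location levels, positivity of
#' concentrations and intakes, the body-fat percentage range, and (as a
#' warning, not an error) whether carbohydrate+protein+fat percent energy at
#' Atwater factors 4/4/9 exceeds 105% of reported energy.
#'
#' @param cohort Data frame of per-subject phenotype/diet values.
#' @param age_bounds Inclusion bounds on age in years.
#' @return List with `ok`, character vectors `errors` and `warnings`.
#' @export
validate_cohort <- function(cohort, age_bounds = c(25, 60)) {
  errors <- character(0)
  warnings <- character(0)

  missing_cols <- setdiff(.COHORT_REQUIRED, names(cohort))
  if (length(missing_cols))
    return(list(ok = FALSE,
                errors = paste("missing required column:", missing_cols),
                warnings = warnings))

  chk <- function(cond, msg) if (any(cond, na.rm = TRUE))
    errors <<- c(errors, sprintf("%s (%d subject(s))", msg,
                                 sum(cond, na.rm = TRUE)))
  chk(cohort$age < age_bounds[1] | cohort$age > age_bounds[2],
      sprintf("age outside [%g, %g]", age_bounds[1], age_bounds[2]))
  chk(!cohort$location %in% c("urban", "rural"),
      "location not one of urban/rural")
  chk(cohort$bfp <= 0 | cohort$bfp >= 100, "body fat percent outside (0, 100)")
  for (v in c("weight", "height", "wc", "vitd", "glucose", "hba1c",
              "insulin", "tc", "hdl", "tg", "energy", "carb", "protein",
              "fat", "fiber"))
    chk(cohort[[v]] <= 0, paste(v, "not positive"))
  if (anyDuplicated(cohort$subject_id))
    errors <- c(errors, "duplicate subject_id values")

  if (!length(errors)) {
    pe <- percent_energy(cohort$carb, cohort$energy, 4) +
      percent_energy(cohort$protein, cohort$energy, 4) +
      percent_energy(cohort$fat, cohort$energy, 9)
    if (any(pe > 105, na.rm = TRUE))
      warnings <- c(warnings, sprintf(
        "macronutrient energy exceeds 105%% of reported energy for %d subject(s)",
        sum(pe > 105, na.rm = TRUE)))
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

#' Add derived variables to a cohort table
#'
#' Computes BMI from weight/height, LDL-c by Friedewald, and the vitamin D
#' status class. Existing columns of the same names are overwritten.
#'
#' @param cohort Validated cohort data frame.
#' @return The cohort with `bmi`, `ldl` and `vitd_class` columns.
#' @export
derive_phenotypes <- function(cohort) {
  cohort$bmi <- bmi(cohort$weight, cohort$height)
  cohort$ldl <- friedewald_ldl(cohort$tc, cohort$hdl, cohort$tg)
  cohort$vitd_class <- classify_vitd(cohort$vitd)
  cohort
}

#' Apply normality-gated log10 transforms across analysis variables
#'
#' @param cohort Cohort with derived variables.
#' @param variables Columns to gate; defaults to the continuous analysis set.
#' @param alpha Shapiro-Wilk significance level.
#' @return List with `cohort` (columns replaced on the log scale where the
#'   gate fired) and `flags`, a named logical vector of transforms applied.
#' @export
apply_transforms <- function(cohort,
                             variables = c("age", "wc", "bfp", "vitd",
                                           "glucose", "hba1c", "insulin",
                                           "tc", "hdl", "ldl", "tg",
                                           "energy", "carb", "protein",
                                           "fat", "fiber"),
                             alpha = 0.05) {
  flags <- logical(0)
  for (v in variables) {
    res <- log_transform_if_nonnormal(cohort[[v]], alpha)
    cohort[[v]] <- res$values
    flags[v] <- res$transformed
  }
  list(cohort = cohort, flags = flags)
}

#' Analysis sample size from recruitment accounting
#'
#' @param completers Number of subjects completing the study.
#' @param incomplete_genotype Subjects excluded for incomplete genetic data.
#' @param incomplete_diet Subjects excluded for incomplete dietary data.
#' @return Analyzed cohort size.
#' @export
cohort_accounting <- function(completers, incomplete_genotype,
                              incomplete_diet) {
  n <- completers - incomplete_genotype - incomplete_diet
  if (n < 0) stop("exclusions exceed completers")
  n
}
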