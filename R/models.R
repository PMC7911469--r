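#' Association, interaction and ANOVA models
#'
#' One-way ANOVA (from raw data or from published group summaries),
#' covariate-adjusted linear models of outcomes on GRS risk groups, GRS-by-
#' diet interaction models, and tertile-stratified group contrasts. All
#' models are ordinary least squares with intercept and two-sided tests.
#'
#' @name models
NULL

.ADIPOSITY_OUTCOMES <- c("bmi", "wc", "bfp")

#' One-way analysis of variance on raw data
#'
#' Classical between/within decomposition with F on (k-1, N-k) degrees of
#' freedom.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels (coerced to factor), at least 2 groups with
#'   n >= 2 each.
#' @return List `f`, `p`, `df1`, `df2`, `ss_between`, `ss_within`.
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2)) stop("every group needs n >= 2 (offending: ",
                        paste(names(ns)[ns < 2], collapse = ", "), ")")
  n <- length(values)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(f = f, p = p, df1 = df1, df2 = df2,
       ss_between = ssb, ss_within = ssw)
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Given per-group (n, mean, sd) — the form results tables print — rebuilds
#' the between-group sum of squares from the means and the within-group sum
#' of squares from (n-1)*sd^2. Identical to [anova_oneway()] applied to any
#' raw data having those summaries.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param means Numeric vector of group means.
#' @param sds Numeric vector of group standard deviations (>= 0).
#' @return List `f`, `p`, `df1`, `df2`, `ss_between`, `ss_within`.
#' @export
anova_from_summary <- function(n, means, sds) {
  if (length(n) < 2) stop("need at least 2 groups")
  if (length(means) != length(n) || length(sds) != length(n))
    stop("n, means and sds must have equal length")
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- length(n) - 1
  df2 <- N - length(n)
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(f = f, p = p, df1 = df1, df2 = df2,
       ss_between = ssb, ss_within = ssw)
}

# Shared OLS core for association/interaction fits. `focal` names the term
# whose row the caller reports. Errors on degenerate designs before lm().
.fit_ols <- function(data, outcome, rhs_terms, focal, adjustment,
                     model_kind, transformed = FALSE) {
  vars <- unique(c(outcome, unlist(lapply(rhs_terms, function(t)
    strsplit(t, ":", fixed = TRUE)[[1]]))))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, vars, drop = FALSE]
  n_used <- nrow(d)
  if (n_used < length(rhs_terms) + 2)
    stop("insufficient data: ", n_used, " complete cases for ",
         length(rhs_terms) + 1, " coefficients")
  for (v in setdiff(vars, outcome)) {
    x <- d[[v]]
    if ((is.numeric(x) && stats::sd(x) == 0) ||
        (!is.numeric(x) && length(unique(x)) == 1L))
      stop("singular design: predictor '", v, "' has zero variance")
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(rhs_terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: aliased coefficients in model for ", outcome)
  ct <- summary(fit)$coefficients
  terms_df <- data.frame(term = rownames(ct),
                         estimate = ct[, 1], se = ct[, 2],
                         t = ct[, 3], p = ct[, 4],
                         row.names = NULL, stringsAsFactors = FALSE)
  focal_rows <- grep(focal, terms_df$term, fixed = TRUE)
  structure(list(outcome = outcome, transformed = transformed,
                 terms = terms_df,
                 focal_term = terms_df$term[utils::tail(focal_rows, 1)],
                 adjustment_set = adjustment, n_used = n_used,
                 model_kind = model_kind, lm = fit),
            class = "grs_fit")
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("%s model: %s%s ~ %s (n = %d)\n", x$model_kind,
              if (x$transformed) "log10 " else "", x$outcome,
              paste(setdiff(x$terms$term, "(Intercept)"), collapse = " + "),
              x$n_used))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Focal-term row of a model fit
#'
#' @param fit A `grs_fit`.
#' @return One-row data frame (term, estimate, se, t, p).
#' @export
focal_row <- function(fit) {
  fit$terms[fit$terms$term == fit$focal_term, , drop = FALSE]
}

#' Covariate-adjusted association between a GRS group and an outcome
#'
#' OLS of the outcome on the risk-group indicator plus the adjustment set.
#' BMI is dropped from the adjustment set automatically when the outcome is
#' itself an adiposity measure (BMI, WC, BFP), so an outcome is never
#' adjusted for itself or a near-alias of itself. Outcomes enter on the
#' scale their transform flag dictates (see [apply_transforms()]).
#'
#' @param data Cohort data frame holding outcome, `grs` column and
#'   covariates (transform-scale values where flagged).
#' @param outcome Name of the outcome column.
#' @param grs Name of the GRS column: a low/high group factor (estimates are
#'   for high vs low) or a numeric score.
#' @param adjustment Covariate names; default age, BMI, location.
#' @param transformed Flag recorded in the fit (outcome on log10 scale).
#' @return A `grs_fit`; the focal term is the GRS coefficient.
#' @export
fit_association <- function(data, outcome, grs = "grs_group",
                            adjustment = c("age", "bmi", "location"),
                            transformed = FALSE) {
  if (outcome %in% .ADIPOSITY_OUTCOMES)
    adjustment <- setdiff(adjustment, "bmi")
  if (outcome %in% adjustment)
    stop("outcome '", outcome, "' cannot appear in its own adjustment set")
  if (is.character(data[[grs]]))
    data[[grs]] <- factor(data[[grs]], levels = c("low", "high"))
  .fit_ols(data, outcome, c(grs, adjustment), focal = grs,
           adjustment = adjustment, model_kind = "association",
           transformed = transformed)
}

#' GRS-by-diet interaction model
#'
#' OLS of the outcome on GRS group, dietary intake, their product, and the
#' adjustment set (which here includes total energy intake by default, since
#' macronutrient grams are energy-bearing). The focal term is the
#' interaction coefficient. The diet variable enters on its transform scale
#' as stored in `data`.
#'
#' @inheritParams fit_association
#' @param diet Name of the dietary exposure column (g/day, or log10 g/day
#'   when flagged).
#' @return A `grs_fit`; the focal term is `grs:diet`.
#' @export
fit_interaction <- function(data, outcome, diet, grs = "grs_group",
                            adjustment = c("age", "bmi", "location",
                                           "energy"),
                            transformed = FALSE) {
  if (outcome %in% .ADIPOSITY_OUTCOMES)
    adjustment <- setdiff(adjustment, "bmi")
  adjustment <- setdiff(adjustment, diet)
  if (outcome %in% adjustment)
    stop("outcome '", outcome, "' cannot appear in its own adjustment set")
  if (is.character(data[[grs]]))
    data[[grs]] <- factor(data[[grs]], levels = c("low", "high"))
  rhs <- c(grs, diet, paste0(grs, ":", diet), adjustment)
  .fit_ols(data, outcome, rhs, focal = ":", adjustment = adjustment,
           model_kind = "interaction", transformed = transformed)
}

#' Tertile-stratified low/high GRS contrast
#'
#' Within each dietary tertile, summarizes the outcome by risk group
#' (mean, SD on the analysis scale) and tests the adjusted group difference
#' with the same covariate rules as [fit_association()]. Cells with fewer
#' than 2 subjects are flagged and their tertile's p-value suppressed.
#'
#' @inheritParams fit_association
#' @param tertiles Factor of tertile labels aligned with `data` rows
#'   (see [assign_tertiles()]).
#' @return Data frame with one row per tertile x group cell: tertile, group,
#'   n, mean, sd, p (the adjusted between-group p, repeated within tertile),
#'   flagged.
#' @export
stratified_contrast <- function(data, outcome, tertiles, grs = "grs_group",
                                adjustment = c("age", "bmi", "location"),
                                transformed = FALSE) {
  stopifnot(nrow(data) == length(tertiles))
  out <- list()
  for (tt in levels(tertiles)) {
    idx <- !is.na(tertiles) & tertiles == tt
    d <- data[idx, , drop = FALSE]
    cell <- do.call(rbind, lapply(c("low", "high"), function(g) {
      v <- d[[outcome]][d[[grs]] == g & !is.na(d[[outcome]])]
      data.frame(tertile = tt, group = g, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    cell$flagged <- cell$n < 2
    p <- NA_real_
    if (!any(cell$flagged)) {
      fit <- tryCatch(
        fit_association(d, outcome, grs, adjustment, transformed),
        error = function(e) NULL)
      if (!is.null(fit)) p <- focal_row(fit)$p
    }
    cell$p <- p
    out[[tt]] <- cell
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
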