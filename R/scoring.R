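#' Unweighted genetic risk scores and median-split risk groups
#'
#' The GRS for a panel is the per-subject sum of risk-allele dosages over the
#' panel's SNPs (each allele contributes 1; no effect-size weights). Scores
#' are dichotomized at an integer threshold derived from the sample median
#' into a "low" and a "high" genetic-risk group.
#'
#' @name scoring
NULL

#' Compute the unweighted GRS for one panel
#'
#' Subjects with any missing call among the panel's SNPs are dropped
#' (complete-case) unless `impute = "mean"`, in which case each missing call
#' is replaced by that SNP's mean observed dosage.
#'
#' @param genotypes A `genotype_matrix` (see [orient_genotypes()]).
#' @param panel Which panel to score: `"vitamin_d"` or `"metabolic"`.
#' @param impute `"complete_case"` (default) or `"mean"`.
#' @return Data frame `subject_id`, `panel`, `score`, with attribute
#'   `dropped` listing subjects excluded for missing calls.
#' @export
compute_grs <- function(genotypes, panel = c("vitamin_d", "metabolic"),
                        impute = c("complete_case", "mean")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  panel <- match.arg(panel)
  impute <- match.arg(impute)

  in_panel <- genotypes$panel$panel == panel
  if (!any(in_panel)) stop("no SNPs with panel = ", panel)
  rsids <- genotypes$panel$rsid[in_panel]
  absent <- setdiff(rsids, colnames(genotypes$dosage))
  if (length(absent))
    stop("panel SNP(s) missing from dosage matrix: ",
         paste(absent, collapse = ", "))

  d <- genotypes$dosage[, rsids, drop = FALSE]
  if (impute == "mean") {
    for (j in seq_len(ncol(d))) {
      m <- mean(d[, j], na.rm = TRUE)
      d[is.na(d[, j]), j] <- m
    }
  }
  score <- rowSums(d)
  keep <- !is.na(score)
  out <- data.frame(subject_id = genotypes$subject_id[keep],
                    panel = rep(panel, sum(keep)),
                    score = unname(score[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- genotypes$subject_id[!keep]
  out
}

#' Integer dichotomization threshold from the sample median
#'
#' The sample median of the integer scores, floored when fractional, so the
#' cutpoint is always an achievable integer score.
#'
#' @param scores Integer GRS values.
#' @return Integer threshold.
#' @export
median_threshold <- function(scores) {
  if (!length(scores)) stop("`scores` is empty")
  as.integer(floor(stats::median(scores)))
}

#' Split GRS values into low/high genetic-risk groups
#'
#' Two boundary conventions are supported: `"le_low"` assigns
#' `score <= threshold` to the low-risk group (the vitamin D panel
#' convention, low = carrying at most the threshold number of risk alleles);
#' `"lt_low"` assigns `score < threshold` to low (the metabolic panel
#' convention, high = carrying at least the threshold).
#'
#' @param scores Integer GRS values.
#' @param threshold Integer cutpoint, normally [median_threshold()].
#' @param boundary_rule `"le_low"` or `"lt_low"`.
#' @return Factor with levels `low`, `high` and attributes `threshold`,
#'   `boundary_rule` and `sizes`. A degenerate split (every subject in one
#'   group) raises a warning and sets attribute `degenerate`.
#' @export
dichotomize <- function(scores, threshold,
                        boundary_rule = c("le_low", "lt_low")) {
  boundary_rule <- match.arg(boundary_rule)
  if (!length(scores)) stop("`scores` is empty")
  low <- if (boundary_rule == "le_low") scores <= threshold
         else scores < threshold
  group <- factor(ifelse(low, "low", "high"), levels = c("low", "high"))
  sizes <- table(group)
  degenerate <- any(sizes == 0)
  if (degenerate)
    warning("degenerate split: all subjects fall in the '",
            names(sizes)[sizes > 0], "' group")
  structure(group, threshold = as.integer(threshold),
            boundary_rule = boundary_rule,
            sizes = c(sizes), degenerate = degenerate)
}

#' Score a panel and median-split it in one step
#'
#' @inheritParams compute_grs
#' @param boundary_rule Boundary convention passed to [dichotomize()];
#'   defaults follow the panel (`le_low` for vitamin_d, `lt_low` for
#'   metabolic).
#' @return Data frame `subject_id`, `panel`, `score`, `group` with
#'   attributes `threshold` and `boundary_rule`.
#' @export
grs_groups <- function(genotypes, panel = c("vitamin_d", "metabolic"),
                       boundary_rule = NULL,
                       impute = c("complete_case", "mean")) {
  panel <- match.arg(panel)
  if (is.null(boundary_rule))
    boundary_rule <- if (panel == "vitamin_d") "le_low" else "lt_low"
  res <- compute_grs(genotypes, panel, impute)
  thr <- median_threshold(res$score)
  grp <- dichotomize(res$score, thr, boundary_rule)
  res$group <- as.character(grp)
  attr(res, "threshold") <- thr
  attr(res, "boundary_rule") <- boundary_rule
  res
}
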