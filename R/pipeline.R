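#' End-to-end analysis pipeline
#'
#' Orchestrates validate -> HWE screen -> GRS construction -> descriptive
#' table -> association models -> interaction models -> tertile-stratified
#' contrasts, and writes a reproducible output bundle (TSV tables plus a
#' JSON run manifest). All results are computed first and files written
#' only at the end, so a failed stage leaves no partial bundle.
#'
#' @name pipeline
NULL

.OUTCOMES <- c("bmi", "wc", "bfp", "vitd", "glucose", "hba1c", "insulin",
               "tc", "hdl", "ldl", "tg")
.DIET_FACTORS <- c("carb", "protein", "fat", "fiber")

.read_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Read a wide genotype table
#'
#' CSV/TSV with a mandatory header: `subject_id` plus one column per rsID,
#' cells as two-character allele pairs or dosage digits; missing calls as
#' empty string, `NA` or `./.`.
#'
#' @param path File path.
#' @param panel A `snp_panel` used to orient the calls.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, panel) {
  raw <- .read_table(path)
  orient_genotypes(raw, panel)
}

#' Read and validate a cohort phenotype/diet table
#'
#' @param path CSV/TSV path following the cohort header contract (see
#'   [validate_cohort()]).
#' @param age_bounds Inclusion bounds on age.
#' @return The validated data frame (validation warnings attached as
#'   attribute `validation_warnings`).
#' @export
read_cohort <- function(path, age_bounds = c(25, 60)) {
  cohort <- .read_table(path)
  v <- validate_cohort(cohort, age_bounds)
  if (!v$ok)
    stop("cohort validation failed: ", paste(v$errors, collapse = "; "))
  attr(cohort, "validation_warnings") <- v$warnings
  cohort
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# Descriptive table stratified by vitamin D class: raw-scale mean +- SD per
# row with the ANOVA p computed on the analysis (transform) scale.
.descriptive_table <- function(raw_cohort, trans_cohort, flags) {
  cls <- raw_cohort$vitd_class
  vars <- c("age", "bmi", "wc", "bfp", "glucose", "hba1c", "insulin",
            "tc", "hdl", "ldl", "tg", "energy", "carb", "protein",
            "fat", "fiber")
  rows <- lapply(vars, function(v) {
    ms <- tapply(raw_cohort[[v]], cls, mean)
    sds <- tapply(raw_cohort[[v]], cls, stats::sd)
    p <- anova_oneway(trans_cohort[[v]], cls)$p
    data.frame(variable = v,
               sufficient = sprintf("%.2f +- %.2f", ms[1], sds[1]),
               insufficient = sprintf("%.2f +- %.2f", ms[2], sds[2]),
               deficient = sprintf("%.2f +- %.2f", ms[3], sds[3]),
               p_anova = p,
               log_scale_test = unname(flags[v] %in% TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.fit_table <- function(fits) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    row <- focal_row(f$fit)
    data.frame(grs_panel = f$panel, outcome = f$fit$outcome,
               diet = if (is.null(f$diet)) NA_character_ else f$diet,
               term = row$term, estimate = row$estimate, se = row$se,
               t = row$t, p = row$p,
               log_outcome = f$fit$transformed,
               n_used = f$fit$n_used,
               adjustment = paste(f$fit$adjustment_set, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  tab$p_bonferroni <- pmin(1, tab$p * nrow(tab))
  tab
}

#' Run the full GRS / gene-diet interaction analysis
#'
#' @param genotype_file Wide genotype CSV/TSV (see [read_genotypes()]).
#' @param cohort_file Cohort phenotype/diet CSV/TSV.
#' @param out_dir Directory for the output bundle (created; existing files
#'   overwritten).
#' @param panel_config Panel YAML/JSON path; defaults to the shipped panel.
#' @param accept_panel Must be TRUE to run on a panel whose config declares
#'   placeholder risk alleles (the shipped default does).
#' @param alpha Significance level for HWE flags, transform gating and for
#'   selecting which interactions get a stratified follow-up table.
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic given the inputs).
#' @param age_bounds Cohort inclusion bounds on age.
#' @return Invisibly, a list with every computed table and the manifest.
#'   Side effect: writes `hwe_report.tsv`, `grs.tsv`, `descriptives.tsv`,
#'   `associations.tsv`, `interactions.tsv`, zero or more
#'   `stratified_<panel>_<diet>_<outcome>.tsv`, and `manifest.json` under
#'   `out_dir`.
#' @export
run_pipeline <- function(genotype_file, cohort_file, out_dir,
                         panel_config = default_panel_path(),
                         accept_panel = FALSE, alpha = 0.05, seed = NULL,
                         age_bounds = c(25, 60)) {
  panel <- load_panel(panel_config)
  if (isTRUE(attr(panel, "placeholder")) && !isTRUE(accept_panel))
    stop("panel stage: the panel config declares placeholder risk alleles; ",
         "confirm them and rerun with accept_panel = TRUE")

  cohort <- tryCatch(read_cohort(cohort_file, age_bounds),
                     error = function(e)
                       stop("cohort stage: ", conditionMessage(e),
                            call. = FALSE))
  genotypes <- tryCatch(read_genotypes(genotype_file, panel),
                        error = function(e)
                          stop("genotype stage: ", conditionMessage(e),
                               call. = FALSE))
  if (!all(cohort$subject_id %in% genotypes$subject_id))
    stop("genotype stage: cohort subjects missing from genotype table")

  hwe <- hwe_report(genotypes, alpha)

  cohort <- derive_phenotypes(cohort)
  tr <- apply_transforms(cohort)
  trans_cohort <- tr$cohort
  flags <- tr$flags

  grs_v <- grs_groups(genotypes, "vitamin_d")
  grs_m <- grs_groups(genotypes, "metabolic")
  grs_tab <- rbind(grs_v, grs_m)

  descr <- .descriptive_table(cohort, trans_cohort, flags)

  # Merge each panel's group labels onto the analysis-scale cohort.
  panel_data <- function(grs) {
    d <- trans_cohort
    d$grs_group <- grs$group[match(d$subject_id, grs$subject_id)]
    d$grs_score <- grs$score[match(d$subject_id, grs$subject_id)]
    d[!is.na(d$grs_group), , drop = FALSE]
  }
  dat <- list(vitamin_d = panel_data(grs_v), metabolic = panel_data(grs_m))

  assoc_fits <- list()
  for (pn in names(dat)) for (oc in .OUTCOMES) {
    fit <- fit_association(dat[[pn]], oc,
                           transformed = unname(flags[oc] %in% TRUE))
    assoc_fits[[paste(pn, oc)]] <- list(panel = pn, diet = NULL, fit = fit)
  }
  assoc_tab <- .fit_table(assoc_fits)

  inter_fits <- list()
  for (pn in names(dat)) for (dv in .DIET_FACTORS) for (oc in .OUTCOMES) {
    fit <- fit_interaction(dat[[pn]], oc, dv,
                           transformed = unname(flags[oc] %in% TRUE))
    inter_fits[[paste(pn, dv, oc)]] <-
      list(panel = pn, diet = dv, fit = fit)
  }
  inter_tab <- .fit_table(inter_fits)

  # Stratified follow-up of nominally significant interactions, mirroring
  # the tertile plots: tertiles of the raw-scale dietary intake, outcome
  # summarized on its analysis scale.
  strat <- list()
  sig <- inter_tab[inter_tab$p < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    pn <- sig$grs_panel[i]; dv <- sig$diet[i]; oc <- sig$outcome[i]
    d <- dat[[pn]]
    raw_diet <- cohort[[dv]][match(d$subject_id, cohort$subject_id)]
    terts <- assign_tertiles(raw_diet)
    tab <- stratified_contrast(d, oc, terts,
                               transformed = unname(flags[oc] %in% TRUE))
    diet_sum <- tertile_summary(raw_diet, terts)
    tab <- merge(tab, stats::setNames(
      diet_sum, c("tertile", "diet_n", "diet_mean", "diet_sd")),
      by = "tertile", sort = FALSE)
    strat[[sprintf("stratified_%s_%s_%s", pn, dv, oc)]] <- tab
  }

  manifest <- list(
    inputs = list(
      genotype_file = basename(genotype_file),
      genotype_md5 = unname(tools::md5sum(genotype_file)),
      cohort_file = basename(cohort_file),
      cohort_md5 = unname(tools::md5sum(cohort_file)),
      panel_config = basename(panel_config),
      panel_md5 = unname(tools::md5sum(panel_config))),
    panel_accepted = isTRUE(accept_panel),
    n_subjects = nrow(cohort),
    thresholds = list(
      vitamin_d = list(threshold = attr(grs_v, "threshold"),
                       boundary_rule = attr(grs_v, "boundary_rule")),
      metabolic = list(threshold = attr(grs_m, "threshold"),
                       boundary_rule = attr(grs_m, "boundary_rule"))),
    transform_flags = as.list(flags),
    adjustment = list(
      association = c("age", "bmi", "location"),
      interaction = c("age", "bmi", "location", "energy"),
      note = "bmi dropped when the outcome is bmi, wc or bfp"),
    alpha = alpha,
    seed = seed,
    package_version = as.character(utils::packageVersion("grsdiet")))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(hwe, file.path(out_dir, "hwe_report.tsv"))
  .write_tsv(grs_tab, file.path(out_dir, "grs.tsv"))
  .write_tsv(descr, file.path(out_dir, "descriptives.tsv"))
  .write_tsv(assoc_tab, file.path(out_dir, "associations.tsv"))
  .write_tsv(inter_tab, file.path(out_dir, "interactions.tsv"))
  for (nm in names(strat))
    .write_tsv(strat[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(hwe = hwe, grs = grs_tab, descriptives = descr,
                 associations = assoc_tab, interactions = inter_tab,
                 stratified = strat, manifest = manifest))
}
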