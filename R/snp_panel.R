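#' SNP panel definitions, genotype orientation and Hardy-Weinberg screening
#'
#' A panel is a set of candidate SNPs, each annotated with the allele whose
#' count enters the genetic risk score (the "risk" allele) and the alternate
#' allele. Two panels are supported: a vitamin D panel (variants in the
#' vitamin D synthesis/transport pathway, risk = 25(OH)D-lowering allele)
#' and a metabolic panel (obesity / type 2 diabetes susceptibility variants).
#'
#' @name snp_panel
NULL

.VALID_ALLELES <- c("A", "C", "G", "T")
.VALID_PANELS <- c("vitamin_d", "metabolic")
.PANEL_FIELDS <- c("rsid", "gene", "risk_allele", "other_allele", "panel")

#' Path to the default SNP panel configuration
#'
#' The shipped panel lists 5 vitamin D pathway SNPs and 10 metabolic disease
#' SNPs. The risk-allele assignments in it are literature-based placeholders:
#' the config carries `placeholder_risk_alleles: true` and pipeline entry
#' points refuse to run on it unless the caller explicitly acknowledges the
#' panel with `accept_panel = TRUE`. Effect-allele orientation is always
#' explicit (never inferred from minor-allele status, which is
#' population-dependent, e.g. DHCR7 rs12785878).
#'
#' @return File path of the YAML panel definition installed with the package.
#' @export
default_panel_path <- function() {
  system.file("extdata", "default_panel.yaml", package = "grsdiet",
              mustWork = TRUE)
}

#' Load and validate a SNP panel configuration
#'
#' @param config Path to a YAML/JSON panel file, or a YAML string. The file
#'   must contain a `snps` list whose entries have exactly the fields
#'   `rsid`, `gene`, `risk_allele`, `other_allele`, `panel`
#'   (panel one of `"vitamin_d"`, `"metabolic"`), and may carry a top-level
#'   logical `placeholder_risk_alleles`.
#' @return A data frame of class `snp_panel` with one row per SNP and an
#'   attribute `placeholder` (TRUE when the config declares its risk alleles
#'   as unconfirmed placeholders).
#' @export
load_panel <- function(config = default_panel_path()) {
  if (length(config) != 1L || !is.character(config))
    stop("`config` must be a single path or YAML string")
  parsed <- if (file.exists(config)) {
    if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else
      yaml::read_yaml(config)
  } else {
    yaml::yaml.load(config)
  }
  if (is.null(parsed$snps))
    stop("panel config must contain a `snps` list")
  entries <- parsed$snps

  rows <- lapply(entries, function(e) {
    extra <- setdiff(names(e), .PANEL_FIELDS)
    if (length(extra))
      stop("unknown panel field(s): ", paste(extra, collapse = ", "))
    missing <- setdiff(.PANEL_FIELDS, names(e))
    if (length(missing))
      stop("panel entry missing field(s): ", paste(missing, collapse = ", "))
    as.data.frame(e[.PANEL_FIELDS], stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)

  bad_allele <- !(panel$risk_allele %in% .VALID_ALLELES) |
    !(panel$other_allele %in% .VALID_ALLELES)
  if (any(bad_allele))
    stop("invalid allele character for ",
         paste(panel$rsid[bad_allele], collapse = ", "),
         " (alleles must be one of A, C, G, T)")
  same <- panel$risk_allele == panel$other_allele
  if (any(same))
    stop("risk and other allele identical for ",
         paste(panel$rsid[same], collapse = ", "))
  dup <- duplicated(panel$rsid)
  if (any(dup))
    stop("duplicate rsID in panel: ",
         paste(unique(panel$rsid[dup]), collapse = ", "))
  if (!all(panel$panel %in% .VALID_PANELS))
    stop("panel membership must be one of: ",
         paste(.VALID_PANELS, collapse = ", "))

  structure(panel,
            placeholder = isTRUE(parsed$placeholder_risk_alleles),
            class = c("snp_panel", "data.frame"))
}

#' Orient a single genotype call to a risk-allele dosage
#'
#' Accepts either a two-character allele pair (e.g. `"AG"`) or an allele
#' dosage 0/1/2 together with the allele it was coded on. The return value is
#' always the count of risk alleles: a dosage `d` coded on the non-risk
#' allele maps to `2 - d`. Missing calls (`NA`, `""`, `"NA"`, `"./."`) return
#' `NA`.
#'
#' @param call Genotype call: allele pair string, dosage integer, or a
#'   single-digit string.
#' @param risk_allele,other_allele Single nucleotide characters defining the
#'   SNP.
#' @param coded_allele For dosage input, the allele the dosage counts.
#' @param rsid Identifier used in error messages.
#' @return Integer risk-allele dosage in 0:2, or `NA` for a missing call.
#' @export
orient_call <- function(call, risk_allele, other_allele,
                        coded_allele = NULL, rsid = "<snp>") {
  if (length(call) != 1L) stop("`call` must be a single value")
  if (is.na(call)) return(NA_integer_)
  call <- as.character(call)
  if (call %in% c("", "NA", "./.")) return(NA_integer_)

  if (grepl("^[0-2]$", call)) {
    d <- as.integer(call)
    if (is.null(coded_allele))
      stop("dosage call for ", rsid, " requires `coded_allele`")
    if (coded_allele == risk_allele) return(d)
    if (coded_allele == other_allele) return(2L - d)
    stop("allele mismatch at ", rsid, ": coded allele ", coded_allele,
         " is neither ", risk_allele, " nor ", other_allele)
  }

  alleles <- strsplit(call, "")[[1]]
  if (length(alleles) != 2L)
    stop("malformed genotype call '", call, "' at ", rsid)
  known <- alleles %in% c(risk_allele, other_allele)
  if (!all(known))
    stop("allele mismatch at ", rsid, ": call '", call,
         "' contains allele(s) not in {", risk_allele, ",", other_allele, "}")
  sum(alleles == risk_allele)
}

#' Orient a raw genotype table into a risk-allele dosage matrix
#'
#' @param raw Data frame with a `subject_id` column and one column per panel
#'   rsID holding allele-pair strings or dosage digits (dosages are assumed
#'   coded on the risk allele unless `coded_alleles` says otherwise).
#' @param panel A `snp_panel`.
#' @param coded_alleles Optional named character vector (by rsID) giving the
#'   coded allele for dosage-format columns.
#' @return An object of class `genotype_matrix`: a list with `subject_id`,
#'   the `panel`, an integer `dosage` matrix (subjects x SNPs, `NA` where
#'   missing) and a logical `missing` mask.
#' @export
orient_genotypes <- function(raw, panel, coded_alleles = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  if (!"subject_id" %in% names(raw))
    stop("genotype table must have a `subject_id` column")
  absent <- setdiff(panel$rsid, names(raw))
  if (length(absent))
    stop("panel SNP(s) absent from genotype table: ",
         paste(absent, collapse = ", "))

  n <- nrow(raw)
  dosage <- matrix(NA_integer_, nrow = n, ncol = nrow(panel),
                   dimnames = list(NULL, panel$rsid))
  for (j in seq_len(nrow(panel))) {
    rs <- panel$rsid[j]
    coded <- if (!is.null(coded_alleles) && rs %in% names(coded_alleles))
      coded_alleles[[rs]] else panel$risk_allele[j]
    dosage[, j] <- vapply(raw[[rs]], orient_call, integer(1),
                          risk_allele = panel$risk_allele[j],
                          other_allele = panel$other_allele[j],
                          coded_allele = coded, rsid = rs)
  }
  structure(list(subject_id = as.character(raw$subject_id),
                 panel = panel,
                 dosage = dosage,
                 missing = is.na(dosage)),
            class = "genotype_matrix")
}

#' Hardy-Weinberg goodness-of-fit test from genotype counts
#'
#' Pearson chi-square test of observed genotype counts against the
#' expectations n*p^2, 2npq, n*q^2, with the allele frequency estimated from
#' the sample, hence 1 degree of freedom. No continuity correction.
#' Monomorphic SNPs (allele frequency 0 or 1) return chi-square 0, p 1 by
#' convention.
#'
#' @param n_hom_risk,n_het,n_hom_other Genotype counts (risk homozygote,
#'   heterozygote, other homozygote).
#' @param alpha Significance level used for the `in_hwe` flag.
#' @param rsid Optional identifier carried into the result.
#' @return A one-row data frame: rsid, n, the three counts, chi_square,
#'   p_value, in_hwe.
#' @export
hwe_test <- function(n_hom_risk, n_het, n_hom_other, alpha = 0.05,
                     rsid = NA_character_) {
  counts <- c(n_hom_risk, n_het, n_hom_other)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("empty input: all genotype counts are zero")

  p <- (2 * n_hom_risk + n_het) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) {
    chi2 <- 0
    pval <- 1
  } else {
    expected <- n * c(p^2, 2 * p * q, q^2)
    chi2 <- sum((counts - expected)^2 / expected)
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  data.frame(rsid = rsid, n = n,
             n_hom_risk = n_hom_risk, n_het = n_het,
             n_hom_other = n_hom_other,
             chi_square = chi2, p_value = pval,
             in_hwe = pval > alpha,
             stringsAsFactors = FALSE)
}

#' Hardy-Weinberg screen of every SNP in a genotype matrix
#'
#' @param genotypes A `genotype_matrix`.
#' @param alpha Significance level for the `in_hwe` flag.
#' @return Data frame with one row per SNP (see [hwe_test()]).
#' @export
hwe_report <- function(genotypes, alpha = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  rows <- lapply(seq_len(ncol(genotypes$dosage)), function(j) {
    d <- genotypes$dosage[, j]
    d <- d[!is.na(d)]
    hwe_test(sum(d == 2), sum(d == 1), sum(d == 0), alpha = alpha,
             rsid = colnames(genotypes$dosage)[j])
  })
  do.call(rbind, rows)
}
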