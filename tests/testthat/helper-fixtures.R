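# Shared fixtures: construct genotype matrices directly from dosage grids
# so unit tests can bypass file parsing.

default_panel <- load_panel()

make_gm <- function(dosage, panel = default_panel) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  colnames(dosage) <- panel$rsid[seq_len(ncol(dosage))]
  structure(list(subject_id = sprintf("S%03d", seq_len(nrow(dosage))),
                 panel = panel[seq_len(ncol(dosage)), , drop = FALSE],
                 dosage = dosage,
                 missing = is.na(dosage)),
            class = "genotype_matrix")
}

rand_gm <- function(n, panel = default_panel, miss_rate = 0) {
  d <- matrix(sample(0:2, n * nrow(panel), replace = TRUE),
              nrow = n, dimnames = list(NULL, panel$rsid))
  if (miss_rate > 0)
    d[matrix(runif(length(d)) < miss_rate, nrow = n)] <- NA_integer_
  make_gm(d, panel)
}

# Minimal two-SNP panel as a YAML string, for parser-level tests.
tiny_panel_yaml <- function(risk1 = "T", other1 = "C") {
  sprintf(
    "snps:\n  - {rsid: rs1, gene: G1, risk_allele: %s, other_allele: %s, panel: vitamin_d}\n  - {rsid: rs2, gene: G2, risk_allele: A, other_allele: G, panel: metabolic}\n",
    risk1, other1)
}
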