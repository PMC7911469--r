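# Default candidate-SNP panels for the vitamin D and metabolic genetic risk
# scores. Risk-allele assignments below are literature-based PLACEHOLDERS
# (the effect alleles commonly reported by GWAS for 25(OH)D-lowering and
# obesity/T2D risk); confirm them against your genotyping report before an
# analysis run. Pipelines refuse this panel unless accept_panel = TRUE.
placeholder_risk_alleles: true
snps:
  - {rsid: rs12785878, gene: DHCR7,    risk_allele: G, other_allele: T, panel: vitamin_d}
  - {rsid: rs12794714, gene: CYP2R1,   risk_allele: A, other_allele: G, panel: vitamin_d}
  - {rsid: rs6013897,  gene: CYP24A1,  risk_allele: A, other_allele: T, panel: vitamin_d}
  - {rsid: rs2282679,  gene: GC,       risk_allele: C, other_allele: A, panel: vitamin_d}
  - {rsid: rs1801725,  gene: CASR,     risk_allele: T, other_allele: G, panel: vitamin_d}
  - {rsid: rs8050136,  gene: FTO,      risk_allele: A, other_allele: C, panel: metabolic}
  - {rsid: rs9939609,  gene: FTO,      risk_allele: A, other_allele: T, panel: metabolic}
  - {rsid: rs10163409, gene: FTO,      risk_allele: A, other_allele: T, panel: metabolic}
  - {rsid: rs12255372, gene: TCF7L2,   risk_allele: T, other_allele: G, panel: metabolic}
  - {rsid: rs7903146,  gene: TCF7L2,   risk_allele: T, other_allele: C, panel: metabolic}
  - {rsid: rs17782313, gene: MC4R,     risk_allele: C, other_allele: T, panel: metabolic}
  - {rsid: rs2229616,  gene: MC4R,     risk_allele: G, other_allele: A, panel: metabolic}
  - {rsid: rs2237895,  gene: KCNQ1,    risk_allele: C, other_allele: A, panel: metabolic}
  - {rsid: rs2237892,  gene: KCNQ1,    risk_allele: C, other_allele: T, panel: metabolic}
  - {rsid: rs10811661, gene: CDKN2A/B, risk_allele: T, other_allele: C, panel: metabolic}
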