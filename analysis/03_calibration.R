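#!/usr/bin/env Rscript
# Step 3: type-I error and power of the interaction test.
#
# The study itself reports no power calculation, so this step maps the
# empirical rejection rate of the GRS x carbohydrate interaction term over
# a small grid of planted effects and sample sizes (200 replicates per
# cell; Monte-Carlo SE about 0.015 at the null).

suppressPackageStartupMessages(library(grsdiet))

grid <- expand.grid(n = c(110, 500, 1000),
                    beta_interaction = c(0, 8e-4, 2e-3))
cal <- run_calibration(grid, n_reps = 200, alpha = 0.05, seed = 2026L)

dir.create("results", showWarnings = FALSE)
write.table(cal, "results/calibration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Interaction-test rejection rates (alpha = 0.05):\n")
print(cal, row.names = FALSE, digits = 3)
cat("\nNote the n = 110 row at the default effect size: the study-scale\n")
cat("design has limited power, so a single significant interaction there\n")
cat("should be read as hypothesis-generating.\n")
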