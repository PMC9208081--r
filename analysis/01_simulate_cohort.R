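#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 54 organoids screened in triplicate against the four standard-of-care
# drugs (5-FU, oxaliplatin, SN38, cetuximab) on a 6-point, 10-fold dilution
# grid from 10 uM, with matched clinical records (regimen, RECIST-like
# tumor-size change for the palliative subgroup, censored PFS) and genotype
# flags. Ground-truth latent resistance is retained so later stages can be
# checked against it.

library(pdoscore)

cohort <- simulate_cohort(sim_config(seed = 2026))
write_cohort(cohort, "results/cohort")

cat("Cohort written to results/cohort/\n")
cat("  organoids:", nrow(cohort$genotype), "\n")
cat("  viability wells:", nrow(cohort$viability), "\n")
cat("  anti-EGFR hotspot organoids:",
    sum(cohort$genotype$anti_egfr_resistant), "\n")
cat("  RNF43 LoF organoids:", sum(cohort$genotype$rnf43_lof), "\n")
cat("  excluded patients:",
    sum(!is.na(cohort$clinical$excluded_reason)), "\n")
cat("  palliative (RECIST-measured) patients:",
    sum(cohort$clinical$palliative, na.rm = TRUE), "\n")
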