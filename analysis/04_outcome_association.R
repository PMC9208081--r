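#!/usr/bin/env Rscript
# Stage 4: organoid score vs clinical outcome.
#
# On the palliative subset, Spearman correlation between the organoid score
# and the % tumor-size change after first-line therapy; on the palliative
# and overall evaluable groups, Kaplan-Meier curves with the log-rank test
# and the Mantel-Haenszel hazard ratio for high (score >= 2.5) vs low risk.

library(pdoscore)

cohort <- read_cohort("results/cohort")
prof_tbl <- read_profiles("results/profiles.csv")
assoc <- associate_cohort(prof_tbl, cohort$clinical)
write_association(assoc, "results/association.json")

km_high <- assoc$overall$km$high
km_low <- assoc$overall$km$low
km_high$group <- "high"; km_low$group <- "low"
write.csv(rbind(km_high, km_low), "results/km_overall.csv", row.names = FALSE)

cat("Association report -> results/association.json, KM -> results/km_overall.csv\n")
cat(sprintf("Evaluable: %d of %d; palliative: %d\n",
            assoc$n_evaluable, assoc$n_total, assoc$n_palliative))
cat(sprintf("Spearman rho (score vs size change) = %.3f, p = %.4f (%s, n = %d)\n",
            assoc$spearman$estimate, assoc$spearman$p.value,
            assoc$spearman$method, assoc$spearman$n))
cat(sprintf("Log-rank p: palliative %.4f, overall %.4f\n",
            assoc$palliative$logrank$p.value, assoc$overall$logrank$p.value))
hr <- assoc$overall$hazard_ratio
cat(sprintf("MH hazard ratio (high vs low, overall) = %.2f [%.2f, %.2f]\n",
            hr$hr, hr$ci[1], hr$ci[2]))
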