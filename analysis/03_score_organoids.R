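#!/usr/bin/env Rscript
# Stage 3: quartile drug scores and regimen-matched organoid scores.
#
# Splits each drug's cohort-normalized AUC at its quartiles (score 1 = most
# sensitive quarter ... 4 = most resistant), maps every patient's regimen
# to its screened components (FOLFOX -> 5-FU + oxaliplatin, FOLFIRI ->
# 5-FU + SN38, "+ Cetuximab" adds cetuximab, bevacizumab is excluded as
# not evaluable in organoids), and averages the component scores into the
# organoid score; >= 2.5 defines the high-risk class.

library(pdoscore)

curves <- read_curves("results/curves.csv")
cohort <- read_cohort("results/cohort")
prof <- build_profiles(curves, cohort$clinical)
write_profiles(prof$profiles, "results/profiles.csv")
write.csv(prof$drug_scores, "results/drug_scores.csv", row.names = FALSE)

cat("Profiles -> results/profiles.csv, drug scores -> results/drug_scores.csv\n")
cat("Quartile group sizes per drug:\n")
print(with(prof$drug_scores, table(drug, score)))
scored <- prof$profiles[!is.na(prof$profiles$organoid_score), ]
cat(sprintf("Scoreable patients: %d; high-risk (score >= 2.5): %d\n",
            nrow(scored), sum(scored$risk_class == "high")))
refr <- select_refractory(prof$profiles, cohort$clinical)
cat("Refractory organoids (score >= 2.5 + progression):",
    length(refr), "\n")
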