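# pdoscore

Drug screens on patient-derived organoids (PDOs) promise to predict which
chemotherapy a colorectal-cancer patient will actually respond to — but
raw viability curves are not a prediction. `pdoscore` implements the full
quantitative path from plate reader to clinical association for the
*organoid score* methodology: a per-patient summary of in-vitro resistance
against exactly the drugs that patient received.

The package is written for translational researchers running PDO screening
cohorts: it handles viability normalization, curve fitting, AUC scoring,
regimen matching, survival statistics, variant concordance, and
repurposing-screen analysis, and it ships a synthetic-cohort generator so
every stage is testable end-to-end without patient data.

## The method

1. **Dose-response.** Well signals are normalized to the vehicle-control
   mean; each organoid x drug series (6-point, 10-fold dilution from
   10 µM, triplicate) gets a bounded four-parameter logistic fit
   `V(c) = b + (t - b) / (1 + (c/IC50)^h)` and a trapezoidal AUC over
   log10 concentration. IC50s that never cross 0.5 in the tested range are
   right-censored at the top dose, never extrapolated.
2. **Scoring.** Per drug, AUC is normalized by the cohort maximum and the
   cohort is split at quartiles: drug score 1 (most sensitive) to 4 (most
   resistant). The organoid score for a patient is the mean drug score
   over the screened components of their regimen,
   `score = (s_1 + ... + s_n) / n` (FOLFOX → 5-FU + oxaliplatin, FOLFIRI →
   5-FU + SN38, "+ Cetuximab" adds cetuximab; bevacizumab is not evaluable
   in organoids). Score ≥ 2.5 defines the high-risk class.
3. **Outcome association.** Spearman correlation of score vs % tumor-size
   change (RECIST) on the palliative subset; Kaplan-Meier curves, log-rank
   test and Mantel-Haenszel hazard ratio `exp((O1 − E1)/V)` for high vs
   low risk on progression-free survival.
4. **Genomics.** Organoid-tissue variant concordance
   `100·|A∩B|/|A∪B|`, mutation burden with the strict >10/Mb
   hypermutation rule, and therapy-relevant genotype flags (anti-EGFR
   hotspots KRAS/NRAS 12/13/61, BRAF V600E, PIK3CA E545K/H1047R; RNF43
   loss of function; APC truncation).
5. **Repurposing.** For therapy-refractory organoids (score ≥ 2.5 with
   progression) screened against an FDA-oncology library: replicate
   concordance, per-drug Z-scores of AUC, shared-target agreement
   (CDK4/6, PARP, EGFR/HER2), and ranked candidate lists with
   genotype-consistency notes.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic
54-organoid cohort (seed 2026). Running it in order:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_fit_dose_response.R
Rscript analysis/03_score_organoids.R
Rscript analysis/04_outcome_association.R
Rscript analysis/05_genotype_analysis.R
Rscript analysis/06_repurposing_screen.R
```

prints, among other things:

```
Quartile group sizes per drug:
             score
drug           1  2  3  4
  5-FU        14 13 13 14
  cetuximab   14 13 13 14
  oxaliplatin 14 13 13 14
  SN38        14 13 13 14
Scoreable patients: 49; high-risk (score >= 2.5): 31

Spearman rho (score vs size change) = 0.612, p = 0.0041 (t approximation, n = 20)
Log-rank p: palliative 0.1353, overall 0.0863
MH hazard ratio (high vs low, overall) = 1.98 [0.91, 4.33]

Cetuximab auc_norm, hotspot vs wild-type: median 0.934 vs 0.765, Mann-Whitney p = 1.36e-08
LGK974 (PORCN inhibitor) rank: 1 of 57
```

Read: each drug's 54 normalized AUCs split into balanced quartile groups;
the regimen-matched score correlates positively with tumor-size change
(high score = less regression); the high-risk class progresses faster
(HR ≈ 2, CI crossing 1 at this simulated effect size and n); hotspot
organoids are measurably cetuximab-resistant; and the RNF43-mutant
organoid ranks the PORCN inhibitor first among 57 screened drugs.

The same flow is available programmatically:

```r
library(pdoscore)
cohort <- simulate_cohort(sim_config(seed = 1))
curves <- fit_cohort(cohort$viability)          # 4PL fits + AUC + auc_norm
prof   <- build_profiles(curves, cohort$clinical)  # quartile + organoid scores
assoc  <- associate_cohort(prof$profiles, cohort$clinical)
assoc$spearman$estimate
assoc$overall$hazard_ratio$hr
```

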