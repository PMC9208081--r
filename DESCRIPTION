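Package: pdoscore
Title: Organoid Scores from Patient-Derived Organoid Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies drug responses of patient-derived tumor organoid
    (PDO) screens and links them to clinical outcome in colorectal cancer
    cohorts. Normalizes plate viability data, fits four-parameter logistic
    dose-response curves with right-censored IC50 reporting, computes the
    area under the response curve (AUC) and cohort-normalized AUC, assigns
    quartile drug scores and regimen-matched organoid scores, and tests the
    association with tumor regression and progression-free survival
    (Spearman correlation, Kaplan-Meier, log-rank, Mantel-Haenszel hazard
    ratio, Mann-Whitney, Kruskal-Wallis). Also provides organoid-tissue
    variant concordance and hotspot genotype flags from VCF input, and
    repurposing-screen utilities (replicate concordance, per-drug Z-scores,
    shared-target agreement, candidate ranking), together with a
    synthetic-cohort generator that makes the whole pipeline testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
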