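---
title: "Organoid scores from PDO drug screens: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organoid scores from PDO drug screens: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pdoscore` implements a quantitative workflow for patient-derived organoid
(PDO) drug screens in colorectal cancer: raw plate viability is turned into
dose-response summaries, summaries into per-drug quartile scores, scores
into a regimen-matched *organoid score*, and the score into clinical
associations (tumor regression, progression-free survival). This vignette
is the package's account of the underlying models, the parameters that
matter, and the design decisions taken where conventions were genuinely
open.

## Dose-response model

Viability fractions are raw well signals divided by the mean
vehicle-control signal of the same organoid/plate group, so the vehicle
mean maps to exactly 1. Per organoid and drug the package fits a
four-parameter logistic on the log10 dose axis,

$$V(c) = b + \frac{t - b}{1 + (c/\mathrm{IC}_{50})^{h}},$$

by bounded least squares (`minpack.lm::nlsLM`, with an L-BFGS-B fallback),
with box constraints $t \in [0.5, 1.5]$, $b \in [0, 1]$, $h \in [0.1, 10]$
and $\mathrm{IC}_{50}$ within two decades of the tested dose range. Two
numerical choices deserve emphasis:

* **Censored IC50 reporting.** When the fitted curve never crosses 0.5
  within the tested range, the IC50 is reported as right-censored at the
  top dose with a flag, never as the extrapolated value. Extrapolated
  magnitudes from a logistic fit on a bounded grid are fit artifacts that
  can reach absurd orders of magnitude; sensitivity *ranks*, which the
  scoring uses, are preserved by treating censored values as maximal.
* **AUC from measured means, not the fit.** The area under the drug
  response curve is the trapezoidal integral of mean per-dose viability
  (clipped at 0) against log10 concentration, so it exists even when the
  nonlinear fit fails. `auc_span` divides by the log10 dose span, giving a
  unitless value in $[0, t]$; whether published AUCs use raw points or
  fitted curves is generally unstated, and the raw-trapezoid is the
  default here (a fitted-curve mode is not provided).

Concentrations are carried in uM throughout. Antibody drugs (cetuximab)
dosed in mass units are treated as an opaque unit: the AUC and the score
operate on the log span of the dose grid regardless of unit.

## Scoring model

Per drug, `auc_span` is divided by the cohort maximum (`auc_norm`, max
exactly 1), and the cohort is split at the quartiles of `auc_norm`:
score 1 for the most sensitive quarter up to 4 for the most resistant.
Orientation matters: the high-score group is the *resistant* one, which is
what makes high scores associate with poor regression and early
progression.

The quartile convention is deliberately pinned down because it is
otherwise ambiguous: cut points are linear-interpolation quantiles
(`stats::quantile` type 7) and a value equal to a cut point falls in the
lower group. This makes the rule deterministic, gives identical scores to
tied values, and on distinct-valued cohorts produces group sizes that
never differ by more than one (a tested invariant). Boundary organoids can
shift by one group under other conventions; both the convention and the
2.5 risk threshold are exposed as arguments.

The organoid score for a patient is the arithmetic mean of the quartile
scores of the drugs in that patient's regimen,
$\mathrm{score} = \sum_{k=1}^{n} s_k / n$, where $n$ counts the screened
components: FOLFOX contributes 5-FU and oxaliplatin, FOLFIRI contributes
5-FU and SN38 (irinotecan is scored via its active metabolite, the
screened compound), "+ Cetuximab" adds cetuximab. Bevacizumab is excluded
("not evaluable in organoids": its anti-angiogenic action has no readout
in epithelial organoid culture); components without a screened counterpart
(e.g. capecitabine, regorafenib) are excluded with that reason, though the
alias table is editable - a user who accepts capecitabine as a 5-FU
prodrug can add that mapping. Scores of 2.5 or higher define the high-risk
class, boundary inclusive. Drug scores are assigned on the full cohort
before any patient-level exclusions; exclusions (best supportive care, low
organoid-tissue concordance, post-treatment sample, loss to follow-up)
enter the association stage as data flags, never as hard-coded ids.

## Outcome statistics

The association stage computes Spearman's rank correlation between
organoid score and % tumor-size change (palliative subset), and, for high
vs low risk, Kaplan-Meier curves, the log-rank test, and the
Mantel-Haenszel hazard ratio, two-sided throughout. Small-sample paths are
explicit:

* Spearman p is exact by full permutation enumeration for $n \le 9$,
  a t approximation with $n - 2$ df otherwise; the method used is reported.
* Mann-Whitney p is exact by enumeration of all $\binom{n}{n_a}$
  assignments when $n \le 16$ without ties, otherwise a tie-corrected
  normal approximation with continuity correction.
* The log-rank statistic pools ties and uses the hypergeometric variance
  at each event time; p comes from $\chi^2_1$ by default. A
  `p_method = "permutation"` option computes p under the group-label
  permutation null (complete enumeration when feasible, sampling
  otherwise). The $\chi^2$ approximation is known to deviate from the
  discrete permutation null by a few hundredths at $n \approx 12$; for
  cohorts that small the permutation p is the better-calibrated choice.
* The hazard ratio is $\exp((O_1 - E_1)/V)$ from the log-rank
  observed/expected/variance, with
  $\mathrm{CI} = \exp((O_1 - E_1 \pm 1.96\sqrt{V})/V)$ - the convention of
  the graphing software commonly used for such analyses. The
  ratio-of-rates form $(O_1/E_1)/(O_2/E_2)$ is available via
  `method = "oe_ratio"`. The high-risk group is the numerator, so HR > 1
  means faster progression.
* Kruskal-Wallis (quartile-group comparisons) delegates to
  `stats::kruskal.test`.

This estimator of the HR is mildly biased away from 1 for strong effects;
simulation tests bound its recovery (median within [2.4, 3.75] for a true
HR of 3 at 200 per group) rather than assert unbiasedness.

## Variant utilities

Variant calls (consumed from VCF via `vcfR`; effect annotation is read
from INFO fields or a sidecar table, never recomputed) are normalized
before any comparison: "chr" prefixes stripped, alleles trimmed to
parsimony (shared suffix first, then shared prefix with the position
advanced), multi-allelic records split, duplicates collapsed on the
(chrom, pos, ref, alt) key. Organoid-tissue concordance is
$100 \cdot |A \cap B| / |A \cup B|$ - the union denominator is chosen
because it is symmetric and matches a shared/organoid-only/tissue-only
decomposition; a tissue-denominator mode exists because the published
convention is ambiguous. Mutation burden divides the call count by a
callable-exome size that is an explicit input (default 40 Mb, an
assumption, since callable sizes are platform-specific); hypermutation is
a strict `rate > 10` per Mb. Genotype flags are pure functions of the call
set: anti-EGFR resistance from KRAS/NRAS codon 12/13/61 missense, BRAF
V600E, or PIK3CA E545K/H1047R; RNF43 loss of function from frameshift,
nonsense or homozygous deletion; APC truncation from nonsense/frameshift.
Flags always carry their evidence (gene, protein change, VAF) so
conflicting evidence - say an RNF43 frameshift at 90% VAF next to a 5% VAF
APC point mutation - is surfaced for the analyst, never auto-adjudicated.

## Repurposing screen

Replicate screens are compared by per-organoid Pearson correlation across
drugs (affine-invariant, so plate-level scaling between runs is
harmless). Z-scores standardize the replicate-averaged AUC per drug across
organoids with the sample (n-1) standard deviation; negative z marks
relative sensitivity. The per-drug axis is the default because the
scientific question is "which organoid is unusually sensitive to this
drug"; the transpose is available since heatmap conventions differ.
Within-class agreement of shared-target drugs (CDK4/6, PARP, EGFR/HER2)
is summarized as the mean pairwise correlation of member drugs' z-vectors
with a permutation p-value from resampled classes of equal size - this
statistic is the package's own formalization of a visual claim and is
labelled as such. Candidate ranking is a deterministic total order:
ascending z, ties broken by ascending absolute AUC, with
genotype-consistency notes (PORCN inhibitor for RNF43-LoF organoids).

## What the synthetic cohort emulates - and what it does not

No patient-level data are deposited with the study this methodology
serves, so the package ships a generator that reproduces the *statistical
structure* the analysis assumes, at the study's stated geometry: 54
organoids, four standard-of-care drugs, triplicate 6-point 10-fold
dilutions from 10 uM.

Latent resistance is
$\rho_{od} = \mathrm{clip}(w\,u_o + (1-w)\,v_{od} + \text{genotype shifts},\, 0, 1)$
with $u_o, v_{od} \sim \mathrm{Beta}(2,2)$ and mixing weight $w = 0.65$.
The Beta(2,2) choice gives the continuous, non-dichotomous IC50 spread
observed in real PDO panels; the organoid-dominant weight encodes that a
PDO's chemoresistance is largely a property of the organoid rather than
the drug, which is what makes a cross-drug score predictive of outcome at
all at $n \approx 40$. log10 IC50 interpolates a per-drug range linearly
in $\rho$ (ranges placed so simulated IC50s span the tested window; SN38
acts in the nM range), true viability follows the 4PL with top 1, bottom
0.1, hill 1, and observed signals are true viability times
$(1 + N(0, \mathrm{cv}))$, floored at 0, cv 0.10 by default - typical
CellTiter-type assay variability, since no published figure exists.
Genotype effects are additive shifts on $\rho$: +0.4 on cetuximab for
anti-EGFR hotspot organoids (prevalence 0.4), -0.4 on PORCN-class drugs
for RNF43-LoF organoids (prevalence 0.1).

Clinically, % tumor-size change is linear in the mean $\rho$ over the
patient's regimen drugs ($-60 + 80\bar\rho + N(0, 10)$), and PFS is
exponential with hazard
$h_0 \exp(\beta (1 + 3\bar\rho))$, $\beta = \ln 2$, censored uniformly on
[200, 800] days. The hazard acts on the latent 1-4 score scale (the
latent analog of the organoid score) rather than on $\bar\rho$ directly:
$\beta$ is defined per unit of latent *score*, and this is the simplest
proportional-hazards model under which the 2.5-cutoff Kaplan-Meier
analysis has a recoverable signal at $n \approx 40$. The baseline
$h_0 = 1/2000$ per day puts median PFS near 300 days inside the censoring
window. Exclusion flags emulate the study flow: best supportive care with
probability 10/54, other exclusions 4/54, RECIST-measured (palliative)
patients 13/40 of the evaluable group. The screen generator adds a
per-target-class latent factor (weights 0.45 organoid / 0.35 class / 0.20
drug) and heterogeneous per-drug potency windows, so shared-target drugs
correlate and replicate screens reach the high concordance real screens
show; screen noise cv defaults to 0.05.

The generator does **not** emulate: plate-position or edge effects, drug
synergy (combination regimens are scored from single agents), multi-line
therapy sequencing, sequencing reads or variant calling (genotypes enter
as flags), organoid growth kinetics, or any dependence between genotype
and regimen assignment (in the clinic, cetuximab is withheld from
RAS-mutant patients; here regimens are assigned independently). Passing
tests therefore demonstrate that the pipeline recovers the relationships
the generator encodes - direction, calibration, and effect sizes under a
known model - not that real cohorts will show those effect sizes.

## Problem sizes and determinism

The test suite checks exact oracles (hand-computed quartiles, enumeration
p-values, product-limit tables, set arithmetic) and simulation-based
properties at deliberately modest sizes chosen to make the checks sharp
yet quick: 100 simulated curves for IC50 recovery (median absolute log10
error under 0.15 at cv 0.10), 200 seeded cohorts for null calibration of
the association tests (rejection within 5% +/- 3% when the generator's
effects are switched off), 100 seeded cohorts for effect recovery
(positive score-regression correlation and HR > 1 in at least 90% of
seeds under defaults), and 100 replicates of 200-per-group
proportional-hazards data for hazard-ratio recovery. Every stochastic
stage takes an explicit integer seed; a fixed seed reproduces cohorts,
scores and manifests bit-identically, and the pipeline manifest records
md5 hashes of every output so a run can be verified after the fact.

## Known limitations

* The quartile convention can move boundary organoids by one group; any
  comparison with scores computed elsewhere must align conventions first.
* The $\chi^2$ log-rank p is anti-conservative or conservative by a few
  hundredths against the exact permutation null at very small n; use
  `p_method = "permutation"` below roughly n = 20.
* The MH hazard-ratio estimator is biased away from the null for large
  effects and few events; confidence intervals, not the point estimate,
  should carry the interpretation.
* Concordance depends on both call sets passing the same upstream
  filters; the union denominator punishes asymmetric filtering.
* Z-scores across 10 organoids are noisy; candidate ranking is a
  prioritization heuristic, not an effect-size estimate.
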