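# Synthetic-cohort generator. Emulates the study conditions the analysis
# assumes: a ~54-organoid cohort screened against the four standard-of-care
# drugs on a 6-point, 10-fold dilution grid from 10 uM, with replicate
# noise, regimen assignment, RECIST-like tumor-size changes and censored
# PFS times driven by a latent per-organoid resistance, and hotspot / RNF43
# genotypes coupled to specific drug sensitivities.

#' Default standard-of-care drug panel
#'
#' The four screened drugs with per-drug log10-IC50 ranges (log10 uM) that
#' place simulated IC50s across the tested 1e-3 to 10 uM window. SN38
#' (irinotecan's active metabolite) acts in the nM range.
#'
#' @return data.frame with `drug`, `lo`, `hi` (log10 uM).
#' @export
default_drug_panel <- function() {
  data.frame(drug = c("5-FU", "oxaliplatin", "SN38", "cetuximab"),
             lo = c(-1.5, -1.0, -3.0, -1.5),
             hi = c(1.0, 1.3, -0.5, 1.5),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Validated parameter container for [simulate_cohort()]. Defaults encode
#' the emulated study conditions: 54 organoids, four drugs, triplicate
#' 6-point 10-fold dilutions from 10 uM, 10% multiplicative assay noise,
#' tumor-size change = -60 + 80 x (mean latent resistance over the regimen)
#' + N(0, 10), exponential PFS with log hazard ratio ln 2 per unit latent
#' score (the latent analog 1 + 3 x mean resistance of the 1-4 organoid
#' score), uniform censoring on \[200, 800\] days, 40% anti-EGFR hotspot
#' prevalence shifting cetuximab resistance by +0.4, and 10% RNF43
#' loss-of-function shifting PORCN-inhibitor resistance by -0.4.
#'
#' @param n_organoids cohort size.
#' @param drugs data.frame with `drug`, `lo`, `hi` (log10 uM IC50 range).
#' @param n_replicates wells per dose.
#' @param dose_top,n_doses,dilution_factor dose grid, see [dose_grid()].
#' @param noise_cv coefficient of variation of multiplicative viability
#'   noise (>= 0).
#' @param mixing_weight weight of the organoid-level resistance factor vs
#'   drug-specific variation, in \[0, 1\].
#' @param regression_intercept,regression_slope,regression_sd linear link
#'   from mean latent resistance to % tumor-size change.
#' @param baseline_hazard per-day baseline progression hazard.
#' @param score_log_hr log hazard ratio per unit latent score.
#' @param censor_window uniform censoring window in days, `c(min, max)`.
#' @param hotspot_prob,hotspot_shift anti-EGFR hotspot prevalence and its
#'   additive resistance shift on cetuximab.
#' @param rnf43_prob,rnf43_shift RNF43 LoF prevalence and its (negative)
#'   resistance shift on PORCN-class drugs.
#' @param bsc_prob probability a patient received best supportive care only.
#' @param other_exclusion_prob probability of another exclusion flag
#'   (low concordance / post-treatment sample / loss to follow-up).
#' @param palliative_prob probability an evaluable patient is in the
#'   palliative (RECIST-measured) group.
#' @param seed integer RNG seed; fixed seed gives bit-identical cohorts.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_organoids = 54,
                       drugs = default_drug_panel(),
                       n_replicates = 3,
                       dose_top = 10,
                       n_doses = 6,
                       dilution_factor = 10,
                       noise_cv = 0.10,
                       mixing_weight = 0.65,
                       regression_intercept = -60,
                       regression_slope = 80,
                       regression_sd = 10,
                       baseline_hazard = 1 / 2000,
                       score_log_hr = log(2),
                       censor_window = c(200, 800),
                       hotspot_prob = 0.4,
                       hotspot_shift = 0.4,
                       rnf43_prob = 0.1,
                       rnf43_shift = -0.4,
                       bsc_prob = 10 / 54,
                       other_exclusion_prob = 4 / 54,
                       palliative_prob = 13 / 40,
                       seed = 1L) {
  if (!is.numeric(n_organoids) || n_organoids < 1)
    stop("n_organoids must be positive")
  if (!is.data.frame(drugs) || nrow(drugs) == 0)
    stop("drug list must be a non-empty data.frame")
  check_columns(drugs, c("drug", "lo", "hi"), "drug panel")
  if (any(drugs$hi < drugs$lo)) stop("IC50 ranges must be well-ordered (lo <= hi)")
  stopifnot(n_doses >= 2, dilution_factor > 1, noise_cv >= 0,
            n_replicates >= 1, dose_top > 0,
            mixing_weight >= 0, mixing_weight <= 1,
            baseline_hazard > 0,
            length(censor_window) == 2, censor_window[1] > 0,
            censor_window[2] >= censor_window[1])
  for (p in c(hotspot_prob, rnf43_prob, bsc_prob, other_exclusion_prob,
              palliative_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  cfg <- list(n_organoids = as.integer(n_organoids), drugs = drugs,
              n_replicates = as.integer(n_replicates), dose_top = dose_top,
              n_doses = as.integer(n_doses), dilution_factor = dilution_factor,
              noise_cv = noise_cv, mixing_weight = mixing_weight,
              regression_intercept = regression_intercept,
              regression_slope = regression_slope, regression_sd = regression_sd,
              baseline_hazard = baseline_hazard, score_log_hr = score_log_hr,
              censor_window = censor_window,
              hotspot_prob = hotspot_prob, hotspot_shift = hotspot_shift,
              rnf43_prob = rnf43_prob, rnf43_shift = rnf43_shift,
              bsc_prob = bsc_prob, other_exclusion_prob = other_exclusion_prob,
              palliative_prob = palliative_prob, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# clip latent resistance into [0, 1]
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a synthetic organoid cohort
#'
#' Generative model: each organoid o carries a Beta(2,2) resistance factor
#' u\[o\] mixed with drug-specific Beta(2,2) variation v\[o,d\]
#' (`mixing_weight` w): rho\[o,d\] = clip(w u + (1-w) v + genotype shifts).
#' log10 IC50\[o,d\] interpolates the per-drug range linearly in rho; true
#' viability follows a 4PL with top 1, bottom 0.1, hill 1; observed
#' replicate signals are the true viability times (1 + N(0, noise_cv)),
#' floored at 0, with vehicle wells at 1 x noise. Tumor-size change is
#' linear in the mean rho over the patient's regimen drugs plus Gaussian
#' noise; PFS is exponential with hazard
#' `baseline_hazard * exp(score_log_hr * (1 + 3 * mean rho))` - the hazard
#' acts on the latent 1-4 score scale so the 2.5-cutoff comparison has a
#' recoverable signal - censored uniformly.
#'
#' @param config a [sim_config()] object.
#' @return object of class `sim_cohort`: list with `viability` (long table),
#'   `clinical`, `genotype`, ground-truth `rho` and `ic50_um` matrices, and
#'   the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_organoids
  drugs <- config$drugs
  nd <- nrow(drugs)
  ids <- sprintf("O%03d", seq_len(n))

  u <- stats::rbeta(n, 2, 2)
  v <- matrix(stats::rbeta(n * nd, 2, 2), n, nd)
  hotspot <- stats::runif(n) < config$hotspot_prob
  rnf43 <- stats::runif(n) < config$rnf43_prob

  w <- config$mixing_weight
  rho <- w * u + (1 - w) * v
  i_cet <- which(drugs$drug == "cetuximab")
  if (length(i_cet) == 1) rho[, i_cet] <- rho[, i_cet] + hotspot * config$hotspot_shift
  porcn <- which(!is.na(drugs$target_class) & drugs$target_class == "PORCN")
  if ("target_class" %in% names(drugs) && length(porcn) > 0)
    rho[, porcn] <- rho[, porcn] + rnf43 * config$rnf43_shift
  rho <- clip01(rho)
  dimnames(rho) <- list(ids, drugs$drug)

  log_ic50 <- sweep(sweep(rho, 2, drugs$hi - drugs$lo, `*`), 2, drugs$lo, `+`)
  ic50_um <- 10^log_ic50

  doses <- dose_grid(config$dose_top, config$n_doses, config$dilution_factor)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      concentration_um = c(doses, 0),
                      drug = drugs$drug, organoid = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("organoid", "drug", "concentration_um", "replicate")]
  ic <- ic50_um[cbind(match(grid$organoid, ids), match(grid$drug, drugs$drug))]
  true_v <- ifelse(grid$concentration_um == 0, 1,
                   0.1 + 0.9 / (1 + grid$concentration_um / ic))
  noise <- stats::rnorm(nrow(grid), 0, config$noise_cv)
  grid$signal <- pmax(0, true_v * (1 + noise))
  rownames(grid) <- NULL

  regimen_pool <- c("FOLFOX", "FOLFIRI", "FOLFOX + Cetuximab",
                    "FOLFIRI + Cetuximab", "FOLFOX + Bevacizumab",
                    "FOLFIRI + Bevacizumab")
  regimen_prob <- c(0.25, 0.25, 0.15, 0.15, 0.10, 0.10)
  regimen <- sample(regimen_pool, n, replace = TRUE, prob = regimen_prob)
  bsc <- stats::runif(n) < config$bsc_prob
  regimen[bsc] <- "Best supportive care"
  other_reasons <- c("low organoid-tissue concordance", "post-treatment sample",
                     "lost to follow-up")
  other_draw <- stats::runif(n)
  other_pick <- sample(other_reasons, n, replace = TRUE)
  excluded_reason <- rep(NA_character_, n)
  excluded_reason[bsc] <- "best supportive care without chemotherapy"
  oth <- !bsc & other_draw < config$other_exclusion_prob
  excluded_reason[oth] <- other_pick[oth]
  palliative <- !bsc & !oth & stats::runif(n) < config$palliative_prob

  mean_rho <- vapply(seq_len(n), function(i) {
    reg <- map_regimen(regimen[i], screened = drugs$drug)
    if (reg$scoreable) mean(rho[i, reg$components]) else mean(rho[i, ])
  }, numeric(1))

  size_change <- config$regression_intercept +
    config$regression_slope * mean_rho +
    stats::rnorm(n, 0, config$regression_sd)
  latent_score <- 1 + 3 * mean_rho
  hazard <- config$baseline_hazard * exp(config$score_log_hr * latent_score)
  t_event <- stats::rexp(n, rate = hazard)
  t_censor <- stats::runif(n, config$censor_window[1], config$censor_window[2])
  event <- t_event <= t_censor
  pfs <- pmin(t_event, t_censor)
  size_obs <- ifelse(palliative, size_change, NA_real_)
  best_response <- ifelse(is.na(size_obs), NA_character_,
                          ifelse(size_obs <= -30, "PR",
                                 ifelse(size_obs >= 20, "PD", "SD")))

  clinical <- data.frame(
    patient = ids, regimen = regimen, size_change = size_obs,
    pfs_days = pfs, event = event, progression = event,
    best_response = best_response, excluded_reason = excluded_reason,
    palliative = palliative, stringsAsFactors = FALSE)

  genotype <- data.frame(organoid = ids, anti_egfr_resistant = hotspot,
                         rnf43_lof = rnf43, stringsAsFactors = FALSE)

  out <- list(viability = grid, clinical = clinical, genotype = genotype,
              rho = rho, ic50_um = ic50_um, config = config)
  class(out) <- "sim_cohort"
  out
}

#' Default FDA-oncology repurposing screen library
#'
#' A 57-drug library with the shared-target classes used in the screen
#' analysis: three CDK4/6 inhibitors, four PARP inhibitors, eight EGFR/HER2
#' agents, one PORCN inhibitor (LGK974), and 41 further approved oncology
#' drugs without an assigned class. Drug identities and potency windows are
#' synthetic stand-ins for an unpublished library composition.
#'
#' @return data.frame with `drug`, `target_class` (NA when unclassified),
#'   `lo`, `hi` (log10 uM IC50 range).
#' @export
default_screen_library <- function() {
  cdk <- c("ribociclib", "palbociclib", "abemaciclib")
  parp <- c("niraparib", "talazoparib", "rucaparib", "olaparib")
  egfr <- c("gefitinib", "erlotinib", "afatinib", "lapatinib", "osimertinib",
            "dacomitinib", "neratinib", "vandetanib")
  other <- c("imatinib", "dasatinib", "nilotinib", "sunitinib", "sorafenib",
             "pazopanib", "axitinib", "cabozantinib", "regorafenib",
             "lenvatinib", "crizotinib", "ceritinib", "alectinib",
             "vemurafenib", "dabrafenib", "trametinib", "everolimus",
             "temsirolimus", "bortezomib", "carfilzomib", "ixazomib",
             "vorinostat", "romidepsin", "belinostat", "panobinostat",
             "ruxolitinib", "ibrutinib", "idelalisib", "venetoclax",
             "vismodegib", "sonidegib", "docetaxel", "paclitaxel",
             "gemcitabine", "pemetrexed", "topotecan", "etoposide",
             "doxorubicin", "mitoxantrone", "bosutinib", "ponatinib")
  drug <- c(cdk, parp, egfr, "LGK974", other)
  target_class <- c(rep("CDK4/6", 3), rep("PARP", 4), rep("EGFR/HER2", 8),
                    "PORCN", rep(NA_character_, length(other)))
  # heterogeneous per-drug potency windows (log10 uM), as in real libraries;
  # the spread across drugs dominates within-organoid AUC variation
  lo <- seq(-3.5, 0.5, length.out = length(drug))
  lo[drug == "LGK974"] <- -2.5
  data.frame(drug = drug, target_class = target_class,
             lo = lo, hi = lo + 3,
             stringsAsFactors = FALSE)
}

#' Simulate a replicated repurposing drug screen
#'
#' Screens `n_organoids` refractory organoids against a drug library in
#' `n_replicates` independent screens (one well per dose per screen).
#' Latent resistance shares an organoid factor, a per-target-class factor
#' (so drugs with the same target respond similarly), and drug-specific
#' variation; RNF43-LoF organoids get the `rnf43_shift` on PORCN-class
#' drugs. Per-screen AUCs are computed with [compute_auc()] on the
#' simulated viability.
#'
#' @param n_organoids number of organoids screened (default 10).
#' @param library drug library, see [default_screen_library()].
#' @param n_replicates number of independent screens (default 2).
#' @param noise_cv multiplicative viability noise CV (default 0.05).
#' @param dose_top,n_doses,dilution_factor dose grid.
#' @param rnf43_prob RNF43 LoF prevalence when `rnf43_flags` is NULL.
#' @param rnf43_shift resistance shift on PORCN drugs for RNF43-LoF
#'   organoids.
#' @param rnf43_flags optional logical vector fixing the genotype.
#' @param seed RNG seed.
#' @return list with `auc` (list of organoid x drug `auc_span` matrices,
#'   one per screen), `viability` (long tables per screen), `targets`,
#'   `genotype`, ground-truth `rho` and `ic50_um`.
#' @export
simulate_screen <- function(n_organoids = 10,
                            library = default_screen_library(),
                            n_replicates = 2,
                            noise_cv = 0.05,
                            dose_top = 10, n_doses = 6, dilution_factor = 10,
                            rnf43_prob = 0.1, rnf43_shift = -0.4,
                            rnf43_flags = NULL,
                            seed = 1L) {
  stopifnot(n_organoids >= 1, n_replicates >= 1, noise_cv >= 0)
  check_columns(library, c("drug", "target_class", "lo", "hi"), "screen library")
  set.seed(as.integer(seed))
  n <- n_organoids
  nd <- nrow(library)
  ids <- sprintf("R%03d", seq_len(n))
  cls <- ifelse(is.na(library$target_class), library$drug, library$target_class)
  ucls <- unique(cls)

  u <- stats::rbeta(n, 2, 2)
  f <- matrix(stats::rbeta(n * length(ucls), 2, 2), n,
              dimnames = list(ids, ucls))
  v <- matrix(stats::rbeta(n * nd, 2, 2), n, nd)
  if (is.null(rnf43_flags)) rnf43_flags <- stats::runif(n) < rnf43_prob
  stopifnot(length(rnf43_flags) == n)

  rho <- 0.45 * u + 0.35 * f[, cls, drop = FALSE] + 0.20 * v
  porcn <- which(!is.na(library$target_class) & library$target_class == "PORCN")
  if (length(porcn) > 0)
    rho[, porcn] <- rho[, porcn] + rnf43_flags * rnf43_shift
  rho <- clip01(rho)
  dimnames(rho) <- list(ids, library$drug)
  ic50_um <- 10^(sweep(sweep(rho, 2, library$hi - library$lo, `*`),
                       2, library$lo, `+`))

  doses <- dose_grid(dose_top, n_doses, dilution_factor)
  auc <- list(); viab <- list()
  for (r in seq_len(n_replicates)) {
    grid <- expand.grid(concentration_um = c(doses, 0), drug = library$drug,
                        organoid = ids, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("organoid", "drug", "concentration_um")]
    grid$replicate <- r
    ic <- ic50_um[cbind(match(grid$organoid, ids),
                        match(grid$drug, library$drug))]
    true_v <- ifelse(grid$concentration_um == 0, 1,
                     0.1 + 0.9 / (1 + grid$concentration_um / ic))
    grid$signal <- pmax(0, true_v * (1 + stats::rnorm(nrow(grid), 0, noise_cv)))
    nv <- normalize_viability(grid)
    m <- matrix(NA_real_, n, nd, dimnames = list(ids, library$drug))
    pos <- nv[nv$concentration_um > 0, ]
    for (o in ids) for (dr in library$drug) {
      s <- pos[pos$organoid == o & pos$drug == dr, ]
      m[o, dr] <- compute_auc(s$concentration_um, s$viability)$auc_span
    }
    auc[[r]] <- m
    viab[[r]] <- grid
  }
  list(auc = auc, viability = viab, targets = library,
       genotype = data.frame(organoid = ids, rnf43_lof = rnf43_flags,
                             stringsAsFactors = FALSE),
       rho = rho, ic50_um = ic50_um)
}
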