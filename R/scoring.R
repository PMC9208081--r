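#' Quartile drug scores for one drug across the cohort
#'
#' Splits the cohort's normalized AUC values for a single drug into four
#' groups at the quartiles and assigns score 1 (most sensitive quarter,
#' lowest AUC) to 4 (most resistant). Cut points Q1-Q3 are
#' linear-interpolation quantiles (`stats::quantile` type 7); a value equal
#' to a cut point falls in the lower group, so tied values always receive
#' identical scores and the score is non-decreasing in `auc_norm`.
#'
#' @param auc_norm numeric vector (>= 4 finite values), names preserved.
#' @return integer vector of scores in `{1, 2, 3, 4}`.
#' @export
assign_drug_scores <- function(auc_norm) {
  if (any(!is.finite(auc_norm))) {
    bad <- names(auc_norm)[!is.finite(auc_norm)]
    stop("non-finite auc_norm for: ",
         paste(if (length(bad)) bad else which(!is.finite(auc_norm)), collapse = ", "))
  }
  if (length(auc_norm) < 4) stop("need at least 4 organoids to form quartiles")
  q <- stats::quantile(auc_norm, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  score <- 1L + (auc_norm > q[1]) + (auc_norm > q[2]) + (auc_norm > q[3])
  storage.mode(score) <- "integer"
  score
}

#' Default regimen-component alias table
#'
#' Maps clinical regimen components to screened drugs. FOLFOX resolves to
#' 5-FU + oxaliplatin and FOLFIRI to 5-FU + SN38 (irinotecan is scored via
#' its active metabolite SN38, the screened compound). Bevacizumab is
#' excluded as "not evaluable in organoids" (its anti-angiogenic action has
#' no organoid readout); capecitabine (Xeloda) and regorafenib have no
#' screened counterpart and are excluded, but the table is editable so e.g.
#' a capecitabine -> 5-FU alias can be added by the user.
#'
#' @return data.frame with columns `component`, `maps_to`
#'   (semicolon-separated screened drugs, "" when unmapped), `reason`.
#' @export
regimen_aliases <- function() {
  data.frame(
    component = c("FOLFOX", "FOLFIRI", "5-FU", "Oxaliplatin", "Irinotecan",
                  "SN38", "Cetuximab", "Bevacizumab", "Xeloda", "Capecitabine",
                  "Regorafenib"),
    maps_to = c("5-FU;oxaliplatin", "5-FU;SN38", "5-FU", "oxaliplatin", "SN38",
                "SN38", "cetuximab", "", "", "", ""),
    reason = c("", "", "", "", "", "", "", "not evaluable in organoids",
               "no screened counterpart", "no screened counterpart",
               "no screened counterpart"),
    stringsAsFactors = FALSE)
}

#' Parse a clinical regimen string into scoreable drug components
#'
#' Splits the regimen on "+" (and commas), maps each component through the
#' alias table, and partitions components into scoreable screened drugs and
#' excluded components with a reason. Unknown components are excluded with
#' reason "no screened counterpart". A regimen resolving to zero scoreable
#' drugs is flagged not-scoreable rather than raising an error.
#'
#' @param regimen raw regimen string, e.g. `"FOLFOX + Cetuximab"`.
#' @param screened character vector of screened drug names.
#' @param aliases alias table as from [regimen_aliases()].
#' @return list with `regimen`, `components` (screened drugs), `n`,
#'   `excluded` (data.frame component/reason), `scoreable` (logical).
#' @export
map_regimen <- function(regimen,
                        screened = c("5-FU", "oxaliplatin", "SN38", "cetuximab"),
                        aliases = regimen_aliases()) {
  if (!is.character(regimen) || length(regimen) != 1 || !nzchar(trimws(regimen)))
    stop("regimen must be a non-empty string")
  parts <- trimws(strsplit(regimen, "[+,]")[[1]])
  parts <- parts[nzchar(parts)]
  comp <- character(0)
  excl <- data.frame(component = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (p in parts) {
    i <- match(tolower(p), tolower(aliases$component))
    if (is.na(i)) {
      excl <- rbind(excl, data.frame(component = p,
                                     reason = "no screened counterpart"))
      next
    }
    mapped <- strsplit(aliases$maps_to[i], ";")[[1]]
    mapped <- mapped[nzchar(mapped)]
    if (length(mapped) == 0) {
      excl <- rbind(excl, data.frame(component = p, reason = aliases$reason[i]))
      next
    }
    hit <- mapped[mapped %in% screened]
    miss <- setdiff(mapped, screened)
    comp <- c(comp, hit)
    if (length(miss) > 0)
      excl <- rbind(excl, data.frame(component = miss,
                                     reason = "not in screened panel"))
  }
  comp <- unique(comp)
  list(regimen = regimen, components = comp, n = length(comp),
       excluded = excl, scoreable = length(comp) >= 1)
}

#' Regimen-matched organoid score
#'
#' Arithmetic mean of the organoid's quartile drug scores over the n drugs
#' of the matched patient's clinical regimen; always in \[1, 4\].
#'
#' @param drug_scores named numeric vector of component drug scores (each in
#'   1..4); names are drug names.
#' @return the organoid score.
#' @export
organoid_score <- function(drug_scores) {
  if (length(drug_scores) < 1) stop("at least one component drug score required")
  if (any(is.na(drug_scores))) {
    bad <- names(drug_scores)[is.na(drug_scores)]
    stop("missing drug score for: ", paste(bad, collapse = ", "))
  }
  if (any(drug_scores < 1 | drug_scores > 4))
    stop("drug scores must lie in [1, 4]")
  mean(drug_scores)
}

#' Dichotomize the organoid score into risk classes
#'
#' The high-risk class is score >= threshold (boundary inclusive on the
#' high side), default threshold 2.5.
#'
#' @param score organoid score(s) in \[1, 4\].
#' @param threshold classification cut point in (1, 4).
#' @return character vector, `"high"` or `"low"`.
#' @export
classify_risk <- function(score, threshold = 2.5) {
  stopifnot(threshold > 1, threshold < 4)
  if (any(score < 1 | score > 4, na.rm = TRUE)) stop("score out of [1, 4]")
  ifelse(score >= threshold, "high", "low")
}

#' Select therapy-refractory organoids for repurposing screens
#'
#' Returns organoids whose score is at or above the threshold AND whose
#' matched patient had recorded disease progression - the entry criterion
#' for the repurposing screen.
#'
#' @param profiles profiles data.frame with `organoid` and `organoid_score`.
#' @param clinical clinical data.frame with `patient` and logical
#'   `progression`.
#' @param threshold score cut point, default 2.5.
#' @return character vector of organoid ids (possibly empty).
#' @export
select_refractory <- function(profiles, clinical, threshold = 2.5) {
  check_columns(profiles, c("organoid", "organoid_score"), "profiles")
  check_columns(clinical, c("patient", "progression"), "clinical")
  m <- merge(profiles, clinical, by.x = "organoid", by.y = "patient")
  sel <- !is.na(m$organoid_score) & m$organoid_score >= threshold &
    !is.na(m$progression) & m$progression
  sort(as.character(m$organoid[sel]))
}

#' Build per-organoid score profiles for a cohort
#'
#' Assigns quartile drug scores per drug across the full cohort (before any
#' patient exclusions), maps each patient's regimen to scoreable components,
#' and computes the regimen-matched organoid score and risk class.
#'
#' @param curves curves data.frame from [fit_cohort()] (needs `organoid`,
#'   `drug`, `auc_norm`).
#' @param clinical clinical data.frame with `patient` and `regimen`.
#' @param threshold risk-class cut point, default 2.5.
#' @param aliases regimen alias table, see [regimen_aliases()].
#' @return list with `drug_scores` (long data.frame organoid/drug/auc_norm/
#'   score) and `profiles` (one row per patient: components, n, score, risk
#'   class).
#' @export
build_profiles <- function(curves, clinical, threshold = 2.5,
                           aliases = regimen_aliases()) {
  check_columns(curves, c("organoid", "drug", "auc_norm"), "curves")
  check_columns(clinical, c("patient", "regimen"), "clinical")
  screened <- unique(curves$drug)
  ds <- do.call(rbind, lapply(screened, function(dr) {
    sub <- curves[curves$drug == dr, ]
    v <- stats::setNames(sub$auc_norm, sub$organoid)
    data.frame(organoid = sub$organoid, drug = dr, auc_norm = sub$auc_norm,
               score = assign_drug_scores(v), stringsAsFactors = FALSE)
  }))
  rownames(ds) <- NULL
  prof <- lapply(seq_len(nrow(clinical)), function(i) {
    pat <- as.character(clinical$patient[i])
    reg <- map_regimen(as.character(clinical$regimen[i]), screened, aliases)
    if (!reg$scoreable) {
      return(data.frame(organoid = pat, regimen = reg$regimen,
                        components = "", n_components = 0L,
                        organoid_score = NA_real_, risk_class = NA_character_,
                        stringsAsFactors = FALSE))
    }
    sc <- ds$score[ds$organoid == pat]
    names(sc) <- ds$drug[ds$organoid == pat]
    miss <- setdiff(reg$components, names(sc))
    if (length(miss) > 0)
      stop("no drug score for organoid ", pat, ", drug(s): ",
           paste(miss, collapse = ", "))
    s <- organoid_score(sc[reg$components])
    data.frame(organoid = pat, regimen = reg$regimen,
               components = paste(reg$components, collapse = ";"),
               n_components = reg$n, organoid_score = s,
               risk_class = classify_risk(s, threshold),
               stringsAsFactors = FALSE)
  })
  list(drug_scores = ds, profiles = do.call(rbind, prof))
}
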