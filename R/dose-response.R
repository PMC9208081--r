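#' Four-parameter logistic dose-response model
#'
#' Evaluates the 4PL viability model
#' \deqn{V(c) = bottom + (top - bottom) / (1 + (c / IC50)^{hill})}
#' used throughout the package. At `c = 0` the model returns `top`; at
#' `c = IC50` it returns the midpoint `(top + bottom) / 2`.
#'
#' @param conc concentration vector (same unit as `ic50`, conventionally uM).
#' @param top,bottom asymptotic viability fractions at zero / infinite dose.
#' @param hill Hill slope (> 0 for a decreasing curve).
#' @param ic50 half-maximal inhibitory concentration.
#' @return numeric vector of viability fractions.
#' @export
fourpl <- function(conc, top = 1, bottom = 0, hill = 1, ic50 = 1) {
  stopifnot(ic50 > 0)
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Serial-dilution dose grid
#'
#' Descending geometric concentration series, by default the screening
#' layout used for the cohort assays: 6 points, 10-fold dilution from 10 uM.
#'
#' @param dose_top top concentration in uM.
#' @param n_doses number of points (>= 2).
#' @param dilution_factor fold-dilution between consecutive points (> 1).
#' @return numeric vector of concentrations, descending.
#' @export
dose_grid <- function(dose_top = 10, n_doses = 6, dilution_factor = 10) {
  stopifnot(n_doses >= 2, dilution_factor > 1, dose_top > 0)
  dose_top / dilution_factor^(seq_len(n_doses) - 1)
}

#' Normalize raw well signals to viability fractions
#'
#' Divides each well's raw signal (e.g. CellTiter-Glo luminescence) by the
#' mean vehicle-control signal of its plate group, so the vehicle mean maps
#' to exactly 1. Vehicle wells are rows with `concentration_um == 0`.
#' Grouping is by `organoid` and, when present, `plate`.
#'
#' @param tbl viability table with columns `organoid`, `drug`,
#'   `concentration_um`, `replicate`, `signal` and optionally `plate`.
#' @return the table with an added `viability` column. Fractions are not
#'   clipped; inputs are required to be non-negative.
#' @export
normalize_viability <- function(tbl) {
  check_columns(tbl, c("organoid", "drug", "concentration_um", "replicate", "signal"),
                "viability table")
  if (any(tbl$concentration_um < 0)) stop("negative concentrations in viability table")
  if (any(!is.finite(tbl$signal)) || any(tbl$signal < 0))
    stop("raw signals must be finite and non-negative")
  grp <- if ("plate" %in% names(tbl)) {
    paste(tbl$organoid, tbl$plate, sep = "\r")
  } else {
    as.character(tbl$organoid)
  }
  veh <- tbl$concentration_um == 0
  veh_mean <- tapply(tbl$signal[veh], grp[veh], mean)
  missing <- setdiff(unique(grp), names(veh_mean))
  if (length(missing) > 0)
    stop("no vehicle-control wells for group(s): ",
         paste(gsub("\r", "/", missing), collapse = ", "))
  if (any(veh_mean == 0))
    stop("zero vehicle-control mean for group(s): ",
         paste(gsub("\r", "/", names(veh_mean)[veh_mean == 0]), collapse = ", "))
  tbl$viability <- tbl$signal / as.numeric(veh_mean[grp])
  tbl
}

#' Fit a four-parameter logistic curve to viability data
#'
#' Least-squares 4PL fit on the log10-dose axis with box constraints:
#' top in \[0.5, 1.5\], bottom in \[0, 1\], hill in \[0.1, 10\], IC50 in
#' \[dose_min/100, dose_max*100\]. When the fitted curve never crosses 0.5
#' within the tested dose range, the IC50 is reported right-censored at the
#' top dose (`ic50_censored = TRUE`) instead of an extrapolated value:
#' extrapolated magnitudes are fit artifacts, while sensitivity ranks are
#' preserved by treating censored values as maximal.
#'
#' @param dose_um positive dose vector (uM), replicate-level allowed.
#' @param viability viability fractions paired with `dose_um`.
#' @return list with `top`, `bottom`, `hill`, `ic50`, `ic50_censored`.
#' @export
fit_curve <- function(dose_um, viability) {
  if (length(dose_um) != length(viability)) stop("dose and viability lengths differ")
  if (any(!is.finite(viability))) stop("non-finite viability fractions")
  keep <- dose_um > 0
  d <- dose_um[keep]
  v <- viability[keep]
  if (length(unique(d)) < 4) stop("at least 4 distinct positive doses required")
  l <- log10(d)
  lo <- c(top = 0.5, bottom = 0, hill = 0.1, lic50 = log10(min(d)) - 2)
  hi <- c(top = 1.5, bottom = 1, hill = 10, lic50 = log10(max(d)) + 2)
  mid <- (max(v) + min(v)) / 2
  start <- c(top = min(max(max(v), 0.5), 1.5),
             bottom = min(max(min(v), 0), 1),
             hill = 1,
             lic50 = l[which.min(abs(v - mid))])
  start <- pmin(pmax(start, lo + 1e-8), hi - 1e-8)
  sse <- function(p) sum((v - (p[2] + (p[1] - p[2]) / (1 + 10^(p[3] * (l - p[4])))))^2)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + 10^(hill * (l - lic50))),
      start = as.list(start), lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(m)
  }, error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit))) {
    opt <- stats::optim(start, sse, method = "L-BFGS-B", lower = lo, upper = hi)
    fit <- opt$par
  }
  top <- unname(fit["top"]); bottom <- unname(fit["bottom"])
  hill <- unname(fit["hill"]); ic50 <- 10^unname(fit["lic50"])
  censored <- fourpl(max(d), top, bottom, hill, ic50) > 0.5
  if (censored) ic50 <- max(d)
  list(top = top, bottom = bottom, hill = hill,
       ic50 = ic50, ic50_censored = censored)
}

#' Area under the measured dose-response curve
#'
#' Trapezoidal integral of mean viability fraction against log10
#' concentration across the measured dose grid (not the fitted curve), so
#' the AUC exists even when curve fitting fails. Viability is clipped at 0
#' before integration. `auc_span` rescales by the log10 dose span, giving a
#' unitless value in \[0, top\].
#'
#' @param dose_um positive dose vector (uM), one entry per dose.
#' @param viability mean viability fraction at each dose.
#' @return list with `auc_raw` (log10-concentration x viability units) and
#'   `auc_span` (`auc_raw` divided by the log10 dose span).
#' @export
compute_auc <- function(dose_um, viability) {
  if (length(dose_um) != length(viability)) stop("dose and viability lengths differ")
  keep <- dose_um > 0
  d <- dose_um[keep]
  v <- viability[keep]
  if (length(unique(d)) < 2) stop("at least 2 distinct positive doses required")
  if (any(!is.finite(v))) stop("non-finite viability fractions")
  ord <- order(d)
  l <- log10(d[ord])
  v <- pmax(v[ord], 0)
  n <- length(l)
  auc_raw <- sum(diff(l) * (v[-1] + v[-n]) / 2)
  list(auc_raw = auc_raw, auc_span = auc_raw / (l[n] - l[1]))
}

#' Cohort-normalized AUC
#'
#' Divides each organoid's `auc_span` for one drug by the cohort maximum for
#' that drug, so the most resistant organoid(s) get exactly 1 and order is
#' preserved.
#'
#' @param auc_span numeric vector of per-organoid `auc_span` values for a
#'   single drug (names preserved).
#' @return normalized AUC vector in \[0, 1\].
#' @export
normalize_auc_cohort <- function(auc_span) {
  x <- auc_span[is.finite(auc_span)]
  if (length(x) < 1) stop("no finite auc_span values")
  m <- max(x)
  if (m <= 0) stop("cohort maximum AUC is 0: no measurable drug effect")
  auc_span / m
}

#' Fit all organoid-by-drug dose-response curves of a cohort
#'
#' Normalizes raw signals, then per organoid x drug computes mean per-dose
#' viability, the trapezoidal AUC, and (optionally) the bounded 4PL fit.
#' Finally normalizes `auc_span` by the cohort maximum within each drug.
#'
#' @param viability long-format viability table (see
#'   [normalize_viability()]).
#' @param fit logical; fit the 4PL model per curve? Scoring only needs the
#'   AUC, so `fit = FALSE` skips the (slower) nonlinear fits.
#' @return data.frame with one row per organoid x drug: fit parameters (NA
#'   when `fit = FALSE`), `ic50_censored`, `auc_raw`, `auc_span`, `auc_norm`.
#' @export
fit_cohort <- function(viability, fit = TRUE) {
  tbl <- normalize_viability(viability)
  tbl <- tbl[tbl$concentration_um > 0, , drop = FALSE]
  split_key <- interaction(tbl$organoid, tbl$drug, drop = TRUE, sep = "\r")
  pieces <- split(tbl, split_key)
  rows <- lapply(pieces, function(p) {
    means <- tapply(p$viability, p$concentration_um, mean)
    doses <- as.numeric(names(means))
    auc <- compute_auc(doses, as.numeric(means))
    f <- if (fit) fit_curve(p$concentration_um, p$viability) else
      list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
           ic50 = NA_real_, ic50_censored = NA)
    data.frame(organoid = p$organoid[1], drug = p$drug[1],
               top = f$top, bottom = f$bottom, hill = f$hill,
               ic50_um = f$ic50, ic50_censored = f$ic50_censored,
               auc_raw = auc$auc_raw, auc_span = auc$auc_span,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$auc_norm <- NA_real_
  for (dr in unique(out$drug)) {
    i <- out$drug == dr
    out$auc_norm[i] <- normalize_auc_cohort(out$auc_span[i])
  }
  out[order(out$drug, out$organoid), ]
}
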