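# Association and survival statistics used for the score-outcome analyses.
# Exact small-sample paths (enumeration) are implemented directly because
# the reported p-values need a stated, reproducible convention.

# all n! permutations of 1..n as an (n!) x n integer matrix; n <= 9 only
perm_matrix <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  out <- matrix(0L, factorial(n), n)
  blk <- nrow(sub)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[(i - 1) * blk + seq_len(blk), ] <- cbind(i, matrix(rest[sub], blk))
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is computed on average ranks. For n <= 9 the two-sided p-value is
#' exact: the proportion of all n! pairings with |rho| at least the observed
#' |rho|. For larger n the usual t approximation with n - 2 degrees of
#' freedom is used; the method applied is reported.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `estimate` (rho), `p.value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Spearman rho undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 9) {
    rx <- rank(x); ry <- rank(y)
    P <- perm_matrix(n)
    cross <- matrix(ry[P], nrow(P)) %*% rx
    rho_all <- (cross - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tt), n - 2))
    method <- "t approximation"
  }
  list(estimate = unname(rho), p.value = p, n = n, method = method)
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator: at each distinct event time the
#' survival drops by the factor (1 - d/n); censored subjects leave the risk
#' set after their censoring time. S(0) = 1 and S is non-increasing.
#'
#' @param time positive follow-up times (days).
#' @param event logical/0-1 event indicator (FALSE = censored).
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  event <- as.logical(event)
  tt <- sort(unique(time))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(tt, function(t) sum(time == t & !event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = tt, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

# shared O/E/V machinery for the log-rank family (ties pooled,
# hypergeometric variance at each distinct event time)
logrank_oev <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly 2 groups required")
  if (any(table(group) == 0)) stop("a group has zero subjects")
  event <- as.logical(event)
  if (sum(event) < 1) stop("at least one event required")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  g1 <- group == levels(group)[1]
  ev_times <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, V = V, O = sum(event),
       levels = levels(group))
}

#' Two-group log-rank test
#'
#' Standard log-rank test with ties pooled and the hypergeometric variance
#' at each distinct event time. By default p comes from chi-squared with
#' 1 df (no continuity correction). For small samples
#' `p_method = "permutation"` computes p under the group-label permutation
#' null of the same statistic: by complete enumeration of all assignments
#' of group-1 positions when `choose(n, n1)` is at most `max_enum`
#' (deterministic, exact), otherwise from `n_perm` random shuffles.
#'
#' @param time positive follow-up times.
#' @param event event indicator (FALSE = censored).
#' @param group two-level grouping factor.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm random shuffles when enumeration is infeasible.
#' @param max_enum enumeration limit on `choose(n, n1)`.
#' @return list with `chisq`, `p.value`, `p.method`, per-group
#'   observed/expected events, and the variance `V`.
#' @export
logrank_test <- function(time, event, group, p_method = c("chisq", "permutation"),
                         n_perm = 1e5, max_enum = 2e4) {
  p_method <- match.arg(p_method)
  s <- logrank_oev(time, event, group)
  chisq <- if (s$V > 0) (s$O1 - s$E1)^2 / s$V else 0
  if (p_method == "chisq") {
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    pm <- "chisq"
  } else {
    group <- factor(group)
    n <- length(time)
    n1 <- sum(group == levels(group)[1])
    lev <- levels(group)
    stat_for <- function(idx1) {
      g <- rep(lev[2], n); g[idx1] <- lev[1]
      s2 <- logrank_oev(time, event, factor(g, levels = lev))
      if (s2$V > 0) (s2$O1 - s2$E1)^2 / s2$V else 0
    }
    if (choose(n, n1) <= max_enum) {
      stats_null <- apply(utils::combn(n, n1), 2, stat_for)
      p <- mean(stats_null >= chisq - 1e-12)
      pm <- "permutation (exact enumeration)"
    } else {
      stats_null <- vapply(seq_len(n_perm),
                           function(b) stat_for(sample.int(n, n1)), numeric(1))
      p <- (1 + sum(stats_null >= chisq - 1e-12)) / (n_perm + 1)
      pm <- "permutation (sampled)"
    }
  }
  obs <- c(s$O1, s$O - s$O1); names(obs) <- s$levels
  ex <- c(s$E1, s$O - s$E1); names(ex) <- s$levels
  list(chisq = chisq, p.value = p, p.method = pm,
       observed = obs, expected = ex, V = s$V)
}

#' Mantel-Haenszel hazard ratio from log-rank observed/expected counts
#'
#' Default estimator HR = exp((O1 - E1)/V) with 95% CI
#' exp((O1 - E1 +/- z sqrt(V))/V), where O1, E1, V are the log-rank
#' observed, expected and variance for the first factor level (put the
#' high-risk group first so HR > 1 means faster progression). The
#' alternative ratio-of-rates form (O1/E1)/(O2/E2) is available via
#' `method = "oe_ratio"`.
#'
#' @param time positive follow-up times.
#' @param event event indicator.
#' @param group two-level grouping factor; first level is the numerator.
#' @param conf.level confidence level, default 0.95.
#' @param method `"oe"` (default) or `"oe_ratio"`.
#' @return list with `hr`, `ci` (length 2), `conf.level`, `method`.
#' @export
mh_hazard_ratio <- function(time, event, group, conf.level = 0.95,
                            method = c("oe", "oe_ratio")) {
  method <- match.arg(method)
  s <- logrank_oev(time, event, group)
  O2 <- s$O - s$O1; E2 <- s$O - s$E1
  if (min(s$O1, O2) < 1) stop("both groups need at least one event")
  if (s$V <= 0) stop("log-rank variance is zero: hazard ratio undefined")
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  if (method == "oe") {
    hr <- exp((s$O1 - s$E1) / s$V)
    ci <- exp(((s$O1 - s$E1) + c(-1, 1) * z * sqrt(s$V)) / s$V)
  } else {
    hr <- (s$O1 / s$E1) / (O2 / E2)
    se <- sqrt(1 / s$E1 + 1 / E2)
    ci <- exp(log(hr) + c(-1, 1) * z * se)
  }
  list(hr = hr, ci = ci, conf.level = conf.level, method = method)
}

#' Mann-Whitney U test
#'
#' U for the first sample with average-rank ties. The two-sided p-value is
#' exact by enumeration of all C(n, n_a) group assignments when
#' n_a + n_b <= 16 and there are no ties (doubling the smaller tail, capped
#' at 1); otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric samples.
#' @return list with `U`, `p.value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (N <= 16 && !ties) {
    sets <- utils::combn(N, na)
    U_all <- colSums(matrix(seq_len(N)[sets], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(U_all <= U + 1e-9), mean(U_all >= U - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    tab <- table(c(a, b))
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(U = unname(U), p.value = p, method = method)
}

#' Kruskal-Wallis test across three or more groups
#'
#' Thin wrapper around `stats::kruskal.test` (H with tie correction, p from
#' chi-squared with k - 1 df), enforcing the >= 3 non-empty groups contract
#' used for the quartile-group comparisons.
#'
#' @param groups list of >= 3 non-empty numeric vectors.
#' @return list with `H`, `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) stop("need at least 3 groups")
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Cohort-level association of organoid scores with clinical outcome
#'
#' Applies the input exclusion flags, then computes (i) the Spearman
#' correlation of organoid score vs % tumor-size change on the palliative
#' subset, and (ii) Kaplan-Meier curves, log-rank test and Mantel-Haenszel
#' hazard ratio comparing the high (score >= threshold) vs low risk class,
#' on the palliative subset and on all evaluable patients.
#'
#' @param profiles profiles data.frame from [build_profiles()]`$profiles`.
#' @param clinical clinical data.frame with `patient`, `size_change`,
#'   `pfs_days`, `event`, `excluded_reason` (NA/"" when evaluable),
#'   `palliative` (logical).
#' @return list of class `cohort_association` with counts, `spearman`, and
#'   per-subset (`palliative`, `overall`) KM tables, log-rank and HR
#'   results. Degenerate subsets yield NULL entries with a `note`, never an
#'   error.
#' @export
associate_cohort <- function(profiles, clinical) {
  check_columns(profiles, c("organoid", "organoid_score", "risk_class"),
                "profiles")
  check_columns(clinical, c("patient", "size_change", "pfs_days", "event",
                            "excluded_reason", "palliative"), "clinical")
  m <- merge(profiles, clinical, by.x = "organoid", by.y = "patient")
  excluded <- !is.na(m$excluded_reason) & nzchar(as.character(m$excluded_reason))
  evaluable <- !excluded & !is.na(m$organoid_score)
  pall <- evaluable & !is.na(m$palliative) & m$palliative & !is.na(m$size_change)
  res <- list(n_total = nrow(m), n_evaluable = sum(evaluable),
              n_palliative = sum(pall))

  res$spearman <- if (sum(pall) >= 3) {
    spearman_test(m$organoid_score[pall], m$size_change[pall])
  } else NULL

  surv_block <- function(keep) {
    sub <- m[keep & !is.na(m$pfs_days) & !is.na(m$event), , drop = FALSE]
    g <- factor(sub$risk_class, levels = c("high", "low"))
    if (nrow(sub) == 0 || any(table(g) == 0) || sum(sub$event) == 0)
      return(list(note = "degenerate subset: survival comparison skipped",
                  n = as.list(table(g))))
    km <- lapply(split(sub, g), function(s) km_estimate(s$pfs_days, s$event))
    lr <- logrank_test(sub$pfs_days, sub$event, g)
    hr <- tryCatch(mh_hazard_ratio(sub$pfs_days, sub$event, g),
                   error = function(e) list(note = conditionMessage(e)))
    list(n = as.list(table(g)), km = km, logrank = lr, hazard_ratio = hr)
  }
  res$palliative <- surv_block(pall)
  res$overall <- surv_block(evaluable)
  class(res) <- "cohort_association"
  res
}
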