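# FDA-library repurposing screen analysis: replicate concordance, per-drug
# Z-scores, shared-target agreement, and per-organoid candidate ranking.

#' Replicate concordance of two drug screens
#'
#' Pearson correlation across drugs within each organoid between two
#' independent screens, plus the cohort median. Invariant under
#' per-organoid affine transforms of either replicate.
#'
#' @param screen1,screen2 organoid x drug `auc_span` matrices with
#'   identical dimnames.
#' @return list with `per_organoid` (named r vector), `median_r`, and the
#'   paired values retained as `scatter` for reporting.
#' @export
replicate_concordance <- function(screen1, screen2) {
  if (!identical(dimnames(screen1), dimnames(screen2)))
    stop("replicate matrices must share identical row/column sets")
  if (ncol(screen1) < 3) stop("need at least 3 drugs")
  r <- vapply(seq_len(nrow(screen1)), function(i) {
    x <- screen1[i, ]; y <- screen2[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance across drugs for organoid ", rownames(screen1)[i])
    stats::cor(x, y)
  }, numeric(1))
  names(r) <- rownames(screen1)
  list(per_organoid = r, median_r = stats::median(r),
       scatter = data.frame(organoid = rep(rownames(screen1), ncol(screen1)),
                            drug = rep(colnames(screen1), each = nrow(screen1)),
                            rep1 = as.vector(screen1), rep2 = as.vector(screen2),
                            stringsAsFactors = FALSE))
}

#' Per-drug Z-scores of screen AUCs
#'
#' Standardizes the (replicate-averaged) AUC of each drug across organoids:
#' z\[o,d\] = (auc\[o,d\] - mean_o) / sd_o with the sample (n-1) standard
#' deviation. Negative z marks a relatively sensitive organoid. Columns
#' with zero variance are set to NA and flagged. The transposed axis
#' (standardize within organoid across drugs) is available because the
#' convention is ambiguous.
#'
#' @param auc organoid x drug AUC matrix (>= 3 organoids).
#' @param margin `"drug"` (default; standardize each drug across organoids)
#'   or `"organoid"`.
#' @return list with `z` (matrix) and `undefined` (names of zero-variance
#'   columns/rows).
#' @export
auc_zscore <- function(auc, margin = c("drug", "organoid")) {
  margin <- match.arg(margin)
  m <- if (margin == "drug") auc else t(auc)
  if (nrow(m) < 3) stop("need at least 3 organoids per drug")
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  z <- sweep(sweep(m, 2, mu), 2, ifelse(sdv > 0, sdv, NA_real_), `/`)
  undefined <- colnames(m)[sdv == 0]
  z[, sdv == 0] <- NA_real_
  if (margin == "organoid") z <- t(z)
  list(z = z, undefined = undefined)
}

#' Within-class agreement of shared-target drugs
#'
#' For each target class with >= 2 screened drugs, the mean pairwise
#' Pearson correlation of the member drugs' z-score vectors across
#' organoids, with a permutation p-value: the null redraws classes of the
#' same size from all screened drugs. (The summary statistic formalizes the
#' visual "similar response trend" claim; it is added machinery, not a
#' published statistic.)
#'
#' @param z organoid x drug z-score matrix from [auc_zscore()].
#' @param targets data.frame with `drug`, `target_class`.
#' @param n_perm number of label permutations (>= 1000 recommended).
#' @param seed optional RNG seed for the permutation draw.
#' @return list with `classes` (data.frame class / n_drugs / mean_r /
#'   p.value) and `skipped` (classes with a single drug).
#' @export
shared_target_agreement <- function(z, targets, n_perm = 1000, seed = NULL) {
  check_columns(targets, c("drug", "target_class"), "targets")
  if (!is.null(seed)) set.seed(as.integer(seed))
  targets <- targets[!is.na(targets$target_class) &
                       targets$drug %in% colnames(z), , drop = FALSE]
  mean_pair_r <- function(cols) {
    cm <- stats::cor(z[, cols, drop = FALSE], use = "pairwise.complete.obs")
    mean(cm[upper.tri(cm)])
  }
  cls <- split(targets$drug, targets$target_class)
  skipped <- names(cls)[lengths(cls) < 2]
  cls <- cls[lengths(cls) >= 2]
  all_drugs <- colnames(z)
  out <- lapply(names(cls), function(nm) {
    members <- cls[[nm]]
    obs <- mean_pair_r(members)
    null <- vapply(seq_len(n_perm), function(b) {
      mean_pair_r(sample(all_drugs, length(members)))
    }, numeric(1))
    data.frame(class = nm, n_drugs = length(members), mean_r = obs,
               p.value = (1 + sum(null >= obs)) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  list(classes = do.call(rbind, out), skipped = skipped)
}

#' Rank repurposing candidates for one organoid
#'
#' Orders drugs by ascending z-score (most relatively effective first),
#' breaking ties by ascending absolute AUC, and annotates
#' genotype-consistent candidates (e.g. a PORCN inhibitor for an RNF43-LoF
#' organoid).
#'
#' @param z organoid x drug z-score matrix.
#' @param auc organoid x drug AUC matrix (same dimnames).
#' @param organoid organoid id (row name).
#' @param targets optional data.frame with `drug`, `target_class`.
#' @param flags optional named list/row with logical `rnf43_lof`.
#' @return data.frame ordered by rank: `drug`, `z`, `auc_span`, `note`.
#' @export
rank_candidates <- function(z, auc, organoid, targets = NULL, flags = NULL) {
  if (!organoid %in% rownames(z)) stop("organoid not found: ", organoid)
  zo <- z[organoid, ]
  ao <- auc[organoid, colnames(z)]
  ord <- order(zo, abs(ao))
  note <- rep("", ncol(z))
  if (!is.null(targets) && !is.null(flags) && isTRUE(flags$rnf43_lof)) {
    porcn <- targets$drug[!is.na(targets$target_class) &
                            targets$target_class == "PORCN"]
    note[colnames(z) %in% porcn] <-
      "RNF43 LoF: PORCN-inhibitor sensitivity expected"
  }
  data.frame(rank = seq_len(ncol(z)), drug = colnames(z)[ord],
             z = unname(zo[ord]), auc_span = unname(ao[ord]),
             note = note[ord], stringsAsFactors = FALSE)
}
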