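# Variant-level utilities: normalized variant keys, organoid-tissue
# concordance, mutation burden, and therapy-relevant genotype flags.

#' Normalize variant records
#'
#' Strips any "chr" prefix from the chromosome, left-normalizes alleles to
#' their parsimonious form (shared suffix removed first, then shared prefix
#' with the position advanced), derives the variant type from allele
#' lengths, and attaches a `key` of the form `chrom:pos:ref:alt`.
#'
#' @param calls data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return the data.frame with normalized coordinates, a `type` column
#'   (`"SNV"` or `"indel"`) and a `key` column.
#' @export
normalize_variants <- function(calls) {
  check_columns(calls, c("chrom", "pos", "ref", "alt"), "variant calls")
  if (nrow(calls) == 0) {
    calls$type <- character(0); calls$key <- character(0)
    return(calls)
  }
  chrom <- sub("^chr", "", as.character(calls$chrom), ignore.case = TRUE)
  pos <- as.integer(calls$pos)
  ref <- toupper(as.character(calls$ref))
  alt <- toupper(as.character(calls$alt))
  if (any(pos < 1)) stop("positions must be >= 1")
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  if (any(ref == alt)) stop("ref and alt identical after normalization")
  calls$chrom <- chrom; calls$pos <- pos; calls$ref <- ref; calls$alt <- alt
  calls$type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "indel")
  calls$key <- paste(chrom, pos, ref, alt, sep = ":")
  calls
}

#' Load variant calls from a VCF
#'
#' Reads a VCF (v4.x) with `vcfR`, splits multi-allelic records, normalizes
#' and deduplicates calls keyed by (chrom, pos, ref, alt), and attaches
#' effect annotations either from INFO fields (`GENE`, `CLASS`, `PCHANGE`,
#' `VAF`) or from a sidecar annotation table keyed the same way. Records
#' without annotation get effect `"unknown"` with a warning.
#'
#' @param path VCF file path.
#' @param annotation optional data.frame (or CSV path) with columns `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `class`, `protein_change`, `vaf`.
#' @return data.frame of calls: `chrom`, `pos`, `ref`, `alt`, `type`,
#'   `gene`, `class`, `protein_change`, `effect`, `vaf`, `key`.
#' @export
load_variants <- function(path, annotation = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), gene = character(0),
                      class = character(0), protein_change = character(0),
                      effect = character(0), vaf = numeric(0),
                      key = character(0), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty)

  info_field <- function(info, tag) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", tag, "="), info))) > 0
    out[hit] <- sub(paste0("^;?", tag, "="), "", m)
    out
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = a,
        gene = info_field(fix$INFO[i], "GENE"),
        class = info_field(fix$INFO[i], "CLASS"),
        protein_change = info_field(fix$INFO[i], "PCHANGE"),
        vaf = suppressWarnings(as.numeric(info_field(fix$INFO[i], "VAF"))),
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  calls <- normalize_variants(calls)
  calls <- calls[!duplicated(calls$key), , drop = FALSE]

  if (!is.null(annotation)) {
    if (is.character(annotation)) annotation <- utils::read.csv(annotation)
    check_columns(annotation,
                  c("chrom", "pos", "ref", "alt", "gene", "class",
                    "protein_change"), "annotation table")
    ann <- normalize_variants(annotation)
    i <- match(calls$key, ann$key)
    hit <- !is.na(i)
    calls$gene[hit] <- ann$gene[i[hit]]
    calls$class[hit] <- ann$class[i[hit]]
    calls$protein_change[hit] <- ann$protein_change[i[hit]]
    if ("vaf" %in% names(ann)) calls$vaf[hit] <- ann$vaf[i[hit]]
  }
  calls$effect <- ifelse(is.na(calls$class), "unknown",
                         ifelse(calls$class %in% c("silent", "synonymous"),
                                "silent", "nonsilent"))
  if (any(calls$effect == "unknown"))
    warning(sum(calls$effect == "unknown"),
            " call(s) without effect annotation; effect set to 'unknown'")
  rownames(calls) <- NULL
  calls[, names(empty)]
}

#' Organoid-tissue variant concordance
#'
#' Shared-variant concordance between the organoid and matched-tissue call
#' sets, keyed by normalized (chrom, pos, ref, alt). The default
#' denominator is the union of both sets (symmetric); a tissue-denominator
#' mode is available since the convention is ambiguous.
#'
#' @param organoid,tissue variant data.frames with a `key` column (from
#'   [load_variants()] or [normalize_variants()]).
#' @param denominator `"union"` (default) or `"tissue"`.
#' @return list with `overall_pct`, `snv_pct`, `indel_pct`, counts
#'   `n_shared`, `n_organoid_only`, `n_tissue_only`, and `proportions`
#'   (percent of the union in each category, summing to 100).
#' @export
concordance <- function(organoid, tissue, denominator = c("union", "tissue")) {
  denominator <- match.arg(denominator)
  if (!"key" %in% names(organoid)) organoid <- normalize_variants(organoid)
  if (!"key" %in% names(tissue)) tissue <- normalize_variants(tissue)
  ko <- unique(organoid$key); kt <- unique(tissue$key)
  if (length(ko) == 0 && length(kt) == 0)
    stop("both call sets are empty: concordance undefined")
  shared <- intersect(ko, kt)
  uni <- union(ko, kt)
  den_all <- if (denominator == "union") length(uni) else length(kt)
  type_of <- stats::setNames(
    c(organoid$type[match(ko, organoid$key)], tissue$type[match(kt, tissue$key)]),
    c(ko, kt))
  pct_type <- function(tp) {
    keys <- uni[type_of[uni] == tp]
    den <- if (denominator == "union") length(keys) else
      sum(type_of[kt] == tp)
    if (den == 0) return(NA_real_)
    100 * sum(keys %in% shared) / den
  }
  list(overall_pct = 100 * length(shared) / den_all,
       snv_pct = pct_type("SNV"),
       indel_pct = pct_type("indel"),
       n_shared = length(shared),
       n_organoid_only = length(setdiff(ko, kt)),
       n_tissue_only = length(setdiff(kt, ko)),
       proportions = c(
         shared = 100 * length(shared) / length(uni),
         organoid_only = 100 * length(setdiff(ko, kt)) / length(uni),
         tissue_only = 100 * length(setdiff(kt, ko)) / length(uni)))
}

#' Mutation rate per megabase and hypermutation call
#'
#' Rate = number of (coding) calls divided by the callable exome size in
#' Mb. A sample is hypermutated when the rate strictly exceeds 10 per Mb.
#' The callable size is an input (default 40 Mb, a documented assumption).
#'
#' @param calls variant data.frame with an `effect` column.
#' @param callable_mb callable region size in Mb (> 0).
#' @return list with `rate_per_mb`, `n_silent`, `n_nonsilent`,
#'   `hypermutated`.
#' @export
mutation_rate <- function(calls, callable_mb = 40) {
  if (!is.numeric(callable_mb) || callable_mb <= 0)
    stop("callable_mb must be positive")
  n <- nrow(calls)
  eff <- if ("effect" %in% names(calls)) calls$effect else rep("unknown", n)
  list(rate_per_mb = n / callable_mb,
       n_silent = sum(eff == "silent"),
       n_nonsilent = sum(eff == "nonsilent"),
       hypermutated = n / callable_mb > 10)
}

#' Therapy-relevant genotype flags
#'
#' Pure function of the call set:
#' * `anti_egfr_resistant`: any KRAS/NRAS codon 12/13/61 missense, BRAF
#'   V600E, or PIK3CA E545K / H1047R - hotspots associated with cetuximab
#'   resistance;
#' * `rnf43_lof`: RNF43 frameshift, nonsense, or homozygous deletion
#'   (predictive of PORCN-inhibitor sensitivity);
#' * `apc_truncating`: APC nonsense or frameshift.
#' Each true flag carries evidence rows (gene, protein change, VAF) so
#' ambiguous cases (e.g. co-occurring RNF43 LoF and low-VAF APC) are
#' reported, never auto-adjudicated.
#'
#' @param calls variant data.frame from [load_variants()].
#' @return list with the three logical flags and an `evidence` data.frame.
#' @export
genotype_flags <- function(calls) {
  need <- c("gene", "class", "protein_change")
  for (nm in need) if (!nm %in% names(calls)) calls[[nm]] <- NA_character_
  if (!"vaf" %in% names(calls)) calls$vaf <- NA_real_
  if (nrow(calls) > 0 && all(is.na(calls$gene)))
    warning("no gene annotations available; all genotype flags are FALSE")
  g <- calls$gene; cl <- calls$class; pc <- calls$protein_change
  hot <- (!is.na(g) & g %in% c("KRAS", "NRAS") &
            !is.na(cl) & cl == "missense" &
            !is.na(pc) & grepl("^(G12|G13|Q61)", pc)) |
    (!is.na(g) & g == "BRAF" & !is.na(pc) & pc == "V600E") |
    (!is.na(g) & g == "PIK3CA" & !is.na(pc) & pc %in% c("E545K", "H1047R"))
  rnf <- !is.na(g) & g == "RNF43" & !is.na(cl) &
    cl %in% c("frameshift", "nonsense", "homozygous_deletion")
  apc <- !is.na(g) & g == "APC" & !is.na(cl) & cl %in% c("nonsense", "frameshift")
  keep <- hot | rnf | apc
  list(anti_egfr_resistant = any(hot),
       rnf43_lof = any(rnf),
       apc_truncating = any(apc),
       evidence = data.frame(gene = g[keep], protein_change = pc[keep],
                             class = cl[keep], vaf = calls$vaf[keep],
                             stringsAsFactors = FALSE))
}

#' Compare normalized AUC between genotype groups
#'
#' Mann-Whitney test of `auc_norm` for one drug between flagged and
#' unflagged organoids (e.g. cetuximab response by anti-EGFR hotspot
#' status).
#'
#' @param curves curves data.frame with `organoid`, `drug`, `auc_norm`.
#' @param flags data.frame with `organoid` and the logical flag column.
#' @param drug drug to compare.
#' @param flag name of the flag column, default `"anti_egfr_resistant"`.
#' @return list with `U`, `p.value`, group sizes and medians.
#' @export
compare_auc_by_genotype <- function(curves, flags, drug,
                                    flag = "anti_egfr_resistant") {
  check_columns(curves, c("organoid", "drug", "auc_norm"), "curves")
  check_columns(flags, c("organoid", flag), "flags")
  sub <- merge(curves[curves$drug == drug, ], flags, by = "organoid")
  a <- sub$auc_norm[sub[[flag]]]
  b <- sub$auc_norm[!sub[[flag]]]
  if (length(a) == 0 || length(b) == 0)
    stop("both genotype groups must be non-empty for drug ", drug)
  mw <- mann_whitney(a, b)
  c(mw, list(n_flagged = length(a), n_unflagged = length(b),
             median_flagged = stats::median(a),
             median_unflagged = stats::median(b)))
}
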