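# CSV/JSON readers and writers for every table schema in the pipeline.
# Strict header validation, UTF-8, decimal point; unknown extra columns are
# preserved and passed through.

check_columns <- function(df, required, what) {
  if (!is.data.frame(df)) stop(what, " must be a data.frame")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

# validate that a column parses as numeric, reporting offending row numbers
check_numeric_column <- function(df, col, what) {
  x <- df[[col]]
  if (is.numeric(x)) return(invisible(df))
  parsed <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(is.na(parsed) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) > 0)
    stop(what, ": column '", col, "' is not numeric at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df[[col]] <- parsed
  invisible(df)
}

read_csv_checked <- function(path, required, numeric_cols, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  check_columns(df, required, what)
  for (col in intersect(numeric_cols, names(df)))
    df <- check_numeric_column(df, col, what)
  df
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write pipeline tables
#'
#' Paired CSV readers and writers for the pipeline schemas (viability,
#' clinical, curves, profiles, drug scores, genotype flags). Readers
#' validate required headers and numeric columns (reporting the offending
#' row); extra columns round-trip untouched.
#'
#' @param path CSV file path.
#' @param df the table to write.
#' @return readers return the validated data.frame; writers return the path
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_viability <- function(path) {
  df <- read_csv_checked(path,
    c("organoid", "drug", "concentration_um", "replicate", "signal"),
    c("concentration_um", "signal"), "viability table")
  if (nrow(df) > 0 && any(df$concentration_um < 0))
    stop("viability table: negative concentration at row(s) ",
         paste(utils::head(which(df$concentration_um < 0), 5), collapse = ", "))
  df
}

#' @rdname pipeline_io
#' @export
write_viability <- function(df, path) write_csv_plain(df, path)

#' @rdname pipeline_io
#' @export
read_clinical <- function(path) {
  read_csv_checked(path,
    c("patient", "regimen", "size_change", "pfs_days", "event"),
    c("size_change", "pfs_days"), "clinical table")
}

#' @rdname pipeline_io
#' @export
write_clinical <- function(df, path) write_csv_plain(df, path)

#' @rdname pipeline_io
#' @export
read_curves <- function(path) {
  read_csv_checked(path, c("organoid", "drug", "auc_raw", "auc_span", "auc_norm"),
                   c("top", "bottom", "hill", "ic50_um",
                     "auc_raw", "auc_span", "auc_norm"), "curves table")
}

#' @rdname pipeline_io
#' @export
write_curves <- function(df, path) write_csv_plain(df, path)

#' @rdname pipeline_io
#' @export
read_profiles <- function(path) {
  read_csv_checked(path,
    c("organoid", "regimen", "n_components", "organoid_score", "risk_class"),
    c("n_components", "organoid_score"), "profiles table")
}

#' @rdname pipeline_io
#' @export
write_profiles <- function(df, path) write_csv_plain(df, path)

#' @rdname pipeline_io
#' @export
read_genotype <- function(path) {
  read_csv_checked(path, c("organoid"), character(0), "genotype table")
}

#' @rdname pipeline_io
#' @export
write_genotype <- function(df, path) write_csv_plain(df, path)

#' Write a simulated cohort to a directory
#'
#' Emits `viability.csv`, `clinical.csv`, `genotype.csv` and
#' `ground_truth.csv` (long format: organoid, drug, latent resistance rho,
#' true IC50). Round-trips through [read_cohort()].
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()] (or a compatible
#'   list of tables).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_viability(cohort$viability, file.path(dir, "viability.csv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  write_genotype(cohort$genotype, file.path(dir, "genotype.csv"))
  ids <- rownames(cohort$rho); if (is.null(ids)) ids <- character(0)
  drugs <- colnames(cohort$rho); if (is.null(drugs)) drugs <- character(0)
  gt <- data.frame(
    organoid = rep(ids, length(drugs)),
    drug = rep(drugs, each = length(ids)),
    rho = as.vector(cohort$rho),
    ic50_um = as.vector(cohort$ic50_um), stringsAsFactors = FALSE)
  write_csv_plain(gt, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the four cohort CSVs.
#' @return list with `viability`, `clinical`, `genotype`, `rho`, `ic50_um`.
#' @export
read_cohort <- function(dir) {
  viability <- read_viability(file.path(dir, "viability.csv"))
  clinical <- read_clinical(file.path(dir, "clinical.csv"))
  genotype <- read_genotype(file.path(dir, "genotype.csv"))
  gt <- read_csv_checked(file.path(dir, "ground_truth.csv"),
                         c("organoid", "drug", "rho", "ic50_um"),
                         c("rho", "ic50_um"), "ground truth table")
  ids <- unique(gt$organoid); drugs <- unique(gt$drug)
  rho <- ic50 <- matrix(NA_real_, length(ids), length(drugs),
                        dimnames = list(ids, drugs))
  idx <- cbind(match(gt$organoid, ids), match(gt$drug, drugs))
  rho[idx] <- gt$rho
  ic50[idx] <- gt$ic50_um
  out <- list(viability = viability, clinical = clinical, genotype = genotype,
              rho = rho, ic50_um = ic50)
  class(out) <- "sim_cohort"
  out
}

#' Write an association report to JSON
#'
#' Serializes a [associate_cohort()] result (KM tables become arrays of
#' records) with `jsonlite`.
#'
#' @param report `cohort_association` object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_association <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
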