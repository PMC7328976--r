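#' @keywords internal
"_PACKAGE"

# Closed label sets used by record validation.
cancer_levels <- function() {
  c("prostate", "colorectal", "thyroid", "breast", "bladder", "stomach",
    "glioma", "other")
}

ethnicity_levels <- function() {
  c("African", "Asian", "Caucasian", "other")
}

#' Column names of the study-level catalogue
#'
#' The catalogue is a delimited text table with one row per study x variant x
#' cancer combination.  Genotype columns are oriented as (common homozygote,
#' heterozygote, rare homozygote), with the minor allele as the test allele.
#' Studies that report only an adjusted odds ratio carry it in
#' `reported_or` / `reported_ci_low` / `reported_ci_high` and leave the count
#' columns empty.  Microsatellite alleles are represented as biallelic
#' carrier/non-carrier counts (carriers in the "rare homozygote" slot is not
#' used; carriers are split as het = heterozygous carriers when known, else
#' all carriers in `case_het`).
#'
#' @return Character vector of mandatory column names, in canonical order.
#' @export
catalogue_columns <- function() {
  c("study_id", "author", "year", "cancer", "variant", "ethnicity", "design",
    "case_hom_common", "case_het", "case_hom_rare",
    "ctrl_hom_common", "ctrl_het", "ctrl_hom_rare",
    "reported_or", "reported_ci_low", "reported_ci_high", "gwas_replicated")
}

count_cols <- function() {
  c("case_hom_common", "case_het", "case_hom_rare",
    "ctrl_hom_common", "ctrl_het", "ctrl_hom_rare")
}

has_counts <- function(row) {
  all(!is.na(unlist(row[count_cols()])))
}

has_reported <- function(row) {
  !is.na(row$reported_or) && !is.na(row$reported_ci_low) &&
    !is.na(row$reported_ci_high)
}

# Validates one catalogue row; returns NULL if valid, else a reason string.
validate_study_row <- function(row) {
  counts <- unlist(row[count_cols()])
  counts_present <- all(!is.na(counts))
  if (any(!is.na(counts)) && !counts_present)
    return("incomplete genotype counts (all six or none)")
  if (counts_present && any(counts < 0))
    return("negative genotype count")
  if (counts_present && any(counts != round(counts)))
    return("non-integer genotype count")
  reported_present <- has_reported(row)
  if (!counts_present && !reported_present)
    return("neither genotype counts nor reported OR with CI")
  if (reported_present) {
    if (row$reported_or <= 0 || row$reported_ci_low <= 0 ||
        row$reported_ci_high <= 0)
      return("reported OR/CI must be positive")
    if (!(row$reported_ci_low < row$reported_or &&
          row$reported_or < row$reported_ci_high))
      return("reported CI does not bracket reported OR")
  }
  if (is.na(row$year) || row$year < 1990 || row$year > 2100)
    return("year outside [1990, 2100]")
  if (!row$ethnicity %in% ethnicity_levels())
    return(sprintf("ethnicity '%s' not in closed set", row$ethnicity))
  if (!row$cancer %in% cancer_levels())
    return(sprintf("cancer '%s' not in closed set", row$cancer))
  if (counts_present && sum(counts[1:3]) == 0)
    return("all-zero case arm")
  if (counts_present && sum(counts[4:6]) == 0)
    return("all-zero control arm")
  NULL
}

#' Read a study-level catalogue
#'
#' Reads a delimited catalogue of case-control genotype studies, validates
#' each row against the schema invariants, and computes the control-arm
#' Hardy-Weinberg p-value where genotype counts are available.  Malformed
#' rows are collected into a reject report (attached as the `"rejects"`
#' attribute and retrievable with [catalogue_rejects()]), never silently
#' dropped.
#'
#' @param path Path to the catalogue file.
#' @param dialect `"tab"` (default) or `"comma"` field separator.
#' @param hwe_method Method passed to [hwe_test()] for the control-arm check.
#' @return A `study_catalogue` data frame of the valid rows, with columns
#'   [catalogue_columns()] plus `hwe_p`, and a `rejects` attribute: a data
#'   frame with `row` (1-based data row index), `study_id` and `reason`.
#' @seealso [write_catalogue()], [simulate_catalogue()]
#' @export
read_catalogue <- function(path, dialect = c("tab", "comma"),
                           hwe_method = c("chisq", "exact")) {
  dialect <- match.arg(dialect)
  hwe_method <- match.arg(hwe_method)
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  sep <- if (dialect == "tab") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing_cols <- setdiff(catalogue_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("catalogue is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, catalogue_columns(), drop = FALSE]
  df$gwas_replicated <- as.logical(df$gwas_replicated)
  df$gwas_replicated[is.na(df$gwas_replicated)] <- FALSE
  as_study_catalogue(df)
}

#' Build a validated study catalogue from a data frame
#'
#' @param df Data frame with the columns of [catalogue_columns()].
#' @return A `study_catalogue` with invalid rows moved to the `rejects`
#'   attribute.
#' @export
as_study_catalogue <- function(df) {
  missing_cols <- setdiff(catalogue_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  reasons <- vapply(seq_len(nrow(df)), function(i) {
    r <- validate_study_row(df[i, ])
    if (is.null(r)) NA_character_ else r
  }, character(1))
  bad <- !is.na(reasons)
  rejects <- data.frame(row = which(bad),
                        study_id = df$study_id[bad],
                        reason = reasons[bad],
                        stringsAsFactors = FALSE)
  records <- df[!bad, , drop = FALSE]
  rownames(records) <- NULL
  records$hwe_p <- vapply(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    if (has_counts(row)) {
      hwe_test(c(row$ctrl_hom_common, row$ctrl_het, row$ctrl_hom_rare))$p_value
    } else NA_real_
  }, numeric(1))
  class(records) <- c("study_catalogue", "data.frame")
  attr(records, "rejects") <- rejects
  records
}

#' Reject report of a catalogue read
#'
#' @param catalogue A `study_catalogue` from [read_catalogue()].
#' @return Data frame with columns `row`, `study_id`, `reason`.
#' @export
catalogue_rejects <- function(catalogue) {
  r <- attr(catalogue, "rejects")
  if (is.null(r))
    r <- data.frame(row = integer(), study_id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  r
}

#' Write a study catalogue
#'
#' Inverse of [read_catalogue()]: `read_catalogue(write_catalogue(x, f))`
#' reproduces `x` field by field.
#'
#' @param catalogue A `study_catalogue` or compatible data frame.
#' @param path Output file path.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  df <- as.data.frame(catalogue)[, catalogue_columns(), drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @export
print.study_catalogue <- function(x, ...) {
  cat(sprintf("study catalogue: %d records, %d variant-cancer associations\n",
              nrow(x), nrow(unique(as.data.frame(x)[, c("variant", "cancer")]))))
  nrej <- nrow(catalogue_rejects(x))
  if (nrej > 0) cat(sprintf("  (%d rejected rows; see catalogue_rejects())\n", nrej))
  print(utils::head(as.data.frame(x), 5), ...)
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5))
  invisible(x)
}
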