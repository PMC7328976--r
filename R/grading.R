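grade_levels <- function() c("weak", "moderate", "strong")

#' Venice grade: amount of evidence
#'
#' Graded by the sum of test alleles (or genotypes) among cases and
#' controls: A for more than 1000, B for 100 to 1000 inclusive, C below 100.
#'
#' @param evidence_amount Non-negative tally of test alleles.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
grade_amount <- function(evidence_amount) {
  if (is.na(evidence_amount) || evidence_amount < 0)
    stop("evidence_amount must be a non-negative number")
  if (evidence_amount > 1000) "A"
  else if (evidence_amount >= 100) "B"
  else "C"
}

#' Venice grade: replication (heterogeneity)
#'
#' Graded by I-squared: A below 25%, B for 25% to 50% inclusive, C above
#' 50%.
#'
#' @param i_squared_pct I-squared in percent.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
grade_replication <- function(i_squared_pct) {
  if (is.na(i_squared_pct) || i_squared_pct < 0)
    stop("i_squared_pct must be non-negative")
  if (i_squared_pct < 25) "A"
  else if (i_squared_pct <= 50) "B"
  else "C"
}

#' Venice grade: protection from bias
#'
#' C when bias is evident: the Harbord test is significant, the sensitivity
#' suite is unstable, or the pooled effect is small
#' (`max(OR, 1/OR) < 1.15`) without GWAS replication.  A when there is no
#' observable bias: a clearly non-significant Harbord test
#' (p >= 2 x threshold), a stable sensitivity suite, and an effect of
#' magnitude at least 1.15 or GWAS replication.  B otherwise (bias could be
#' present: Harbord unavailable or borderline, or sensitivity not
#' assessable).
#'
#' @param or_pooled Pooled odds ratio.
#' @param gwas_replicated Has the association been replicated by GWAS (or a
#'   GWAS meta-analysis)?
#' @param harbord_p Harbord-test p-value, or `NA` when the test could not be
#'   run.
#' @param sensitivity_stable `TRUE`/`FALSE`, or `NA` when not assessable.
#' @param harbord_threshold Significance cutpoint for declaring small-study
#'   bias (default 0.10).
#' @param bias_evident Optional explicit override (e.g. a judgment call from
#'   outside the mechanized rules).
#' @return `"A"`, `"B"` or `"C"`.
#' @export
grade_bias <- function(or_pooled, gwas_replicated = FALSE, harbord_p = NA,
                       sensitivity_stable = NA, harbord_threshold = 0.10,
                       bias_evident = NA) {
  if (is.na(or_pooled) || or_pooled <= 0) stop("or_pooled must be positive")
  magnitude <- max(or_pooled, 1 / or_pooled)
  small <- magnitude < 1.15 && !isTRUE(gwas_replicated)
  evident <- isTRUE(bias_evident) ||
    (!is.na(harbord_p) && harbord_p < harbord_threshold) ||
    isFALSE(sensitivity_stable)
  if (evident || small) return("C")
  clear_harbord <- !is.na(harbord_p) && harbord_p >= 2 * harbord_threshold
  if (clear_harbord && isTRUE(sensitivity_stable) &&
      (magnitude >= 1.15 || isTRUE(gwas_replicated))) "A" else "B"
}

#' Composite Venice grade
#'
#' Strong if all three grades are A; moderate if all grades are A or B but
#' not all A; weak if any grade is C.
#'
#' @param amount,replication,bias Grades in `{"A","B","C"}`.
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
composite_venice <- function(amount, replication, bias) {
  grades <- c(amount, replication, bias)
  if (!all(grades %in% c("A", "B", "C"))) stop("grades must be A, B or C")
  if (all(grades == "A")) "strong"
  else if (any(grades == "C")) "weak"
  else "moderate"
}

#' FPRP-based upgrade of the composite grade
#'
#' When the FPRP category is `"<0.05"` the cumulative-evidence grade moves up
#' one level (weak to moderate, moderate to strong, strong stays strong);
#' otherwise it is unchanged.
#'
#' @param venice_initial `"strong"`, `"moderate"` or `"weak"`.
#' @param fprp_category One of [fprp_categories()].
#' @return Final grade.
#' @export
apply_fprp_upgrade <- function(venice_initial, fprp_category) {
  if (!venice_initial %in% grade_levels()) stop("invalid initial grade")
  if (!fprp_category %in% fprp_categories()) stop("invalid FPRP category")
  if (fprp_category != "<0.05") return(venice_initial)
  idx <- match(venice_initial, grade_levels())
  grade_levels()[min(idx + 1, 3)]
}

#' Grade one significant association
#'
#' Chains the Venice dimension grades (amount from the evidence tally,
#' replication from I-squared, protection from bias from the Harbord test,
#' sensitivity suite and effect size), the composite rule and the FPRP
#' upgrade.  Only significant associations (p < 0.05) are graded.
#'
#' @param meta `meta_result` for the association.
#' @param harbord `harbord_result` or `NULL` (test unavailable).
#' @param sens `sensitivity_report` or `NULL`.
#' @param fprp `fprp_result`, or an FPRP category string taken as given.
#' @param gwas_replicated GWAS-replication flag for the bias grade.
#' @param harbord_threshold Cutpoint for the bias grade (default 0.10).
#' @param amount_grade Optional explicit amount grade, for summary-mode
#'   inputs whose test-allele tally is unavailable.
#' @return A `credibility_record`: the three dimension grades,
#'   `venice_initial`, `fprp_category`, `final_grade`, and `rationale` (the
#'   rule identifiers fired, in order).
#' @export
grade_association <- function(meta, harbord = NULL, sens = NULL, fprp,
                              gwas_replicated = FALSE,
                              harbord_threshold = 0.10, amount_grade = NULL) {
  if (is.na(meta$p_value) || meta$p_value >= 0.05)
    stop("refusing to grade a non-significant association (p = ",
         format(meta$p_value), "); grading applies to significant findings only")
  rationale <- character()
  if (is.null(amount_grade)) {
    if (is.na(meta$evidence_amount))
      stop("meta result carries no evidence amount; supply amount_grade or use grade_summaries()")
    amount <- grade_amount(meta$evidence_amount)
    rationale <- c(rationale, sprintf("AMOUNT_%s:n=%d", amount,
                                      as.integer(meta$evidence_amount)))
  } else {
    amount <- amount_grade
    rationale <- c(rationale, sprintf("AMOUNT_%s:given", amount))
  }
  k1 <- meta$k < 2
  replication <- if (k1) "C" else grade_replication(meta$i_squared_pct)
  rationale <- c(rationale,
                 if (k1) "REPL_C:single-study"
                 else sprintf("REPL_%s:I2=%.1f", replication, meta$i_squared_pct))
  harbord_p <- if (!is.null(harbord) && !harbord$skipped) harbord$p_value else NA
  stable <- if (!is.null(sens)) sens$stable else NA
  bias <- grade_bias(meta$or_pooled, gwas_replicated, harbord_p, stable,
                     harbord_threshold)
  rationale <- c(rationale, sprintf(
    "BIAS_%s:or=%.3f,harbord_p=%s,stable=%s,gwas=%s", bias, meta$or_pooled,
    ifelse(is.na(harbord_p), "NA", sprintf("%.3f", harbord_p)),
    as.character(stable), gwas_replicated))
  initial <- composite_venice(amount, replication, bias)
  rationale <- c(rationale, sprintf("VENICE_%s", toupper(initial)))
  fprp_category <- if (is.character(fprp)) fprp else fprp$category
  final <- apply_fprp_upgrade(initial, fprp_category)
  if (final != initial)
    rationale <- c(rationale, sprintf("UPGRADE_FPRP:%s->%s", initial, final))
  res <- list(amount_grade = amount, replication_grade = replication,
              bias_grade = bias, venice_initial = initial,
              fprp_category = fprp_category, final_grade = final,
              rationale = rationale)
  class(res) <- "credibility_record"
  res
}

#' @export
print.credibility_record <- function(x, ...) {
  cat(sprintf("Venice grades: amount %s, replication %s, bias %s -> %s\n",
              x$amount_grade, x$replication_grade, x$bias_grade,
              x$venice_initial))
  cat(sprintf("FPRP category %s -> final grade: %s\n",
              x$fprp_category, x$final_grade))
  cat("rationale:", paste(x$rationale, collapse = "; "), "\n")
  invisible(x)
}

#' Grade a table of association summaries
#'
#' Summary-mode grading: for each significant association in a summary table
#' (such as [load_8q24_synopsis()]), derives the replication grade from the
#' I-squared value, takes the amount and bias grades and the FPRP category
#' from the table, applies the composite Venice rule and the FPRP upgrade,
#' and returns the computed initial and final grades alongside the inputs.
#'
#' @param summaries An `association_summary` data frame with columns
#'   `variant`, `cancer`, `significant`, `i_squared_pct`, `amount_grade`,
#'   `bias_grade`, `fprp_category`.
#' @return Data frame of the significant associations with computed
#'   `replication_grade`, `venice_initial` and `final_grade` columns.
#' @examples
#' graded <- grade_summaries(load_8q24_synopsis())
#' table(graded$final_grade)
#' @export
grade_summaries <- function(summaries) {
  sig <- summaries[summaries$significant, , drop = FALSE]
  if (nrow(sig) == 0) stop("no significant associations to grade")
  repl <- vapply(sig$i_squared_pct, grade_replication, character(1))
  initial <- vapply(seq_len(nrow(sig)), function(i)
    composite_venice(sig$amount_grade[i], repl[i], sig$bias_grade[i]),
    character(1))
  final <- vapply(seq_len(nrow(sig)), function(i)
    apply_fprp_upgrade(initial[i], sig$fprp_category[i]), character(1))
  out <- data.frame(variant = sig$variant, cancer = sig$cancer,
                    or_pooled = sig$or_pooled, p_value = sig$p_value,
                    i_squared_pct = sig$i_squared_pct,
                    amount_grade = sig$amount_grade,
                    replication_grade = repl,
                    bias_grade = sig$bias_grade,
                    venice_initial = initial,
                    fprp_category = sig$fprp_category,
                    final_grade = final,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
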