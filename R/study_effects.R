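#' Collapse genotype counts to a 2x2 allele table
#'
#' Genotype triples are ordered (common homozygote, heterozygote, rare
#' homozygote); the minor allele is the test allele.
#'
#' @param counts_case,counts_control Non-negative integer triples.
#' @return Named numeric vector `c(a, b, c, d)`: minor and major allele
#'   counts in cases (`a`, `b`) and controls (`c`, `d`).  Totals equal twice
#'   the genotyped individuals per arm.
#' @examples
#' allele_table_from_genotypes(c(25, 50, 25), c(30, 50, 20))
#' @export
allele_table_from_genotypes <- function(counts_case, counts_control) {
  check_triple <- function(x, arm) {
    if (length(x) != 3 || any(is.na(x)) || any(x < 0))
      stop("invalid genotype triple in ", arm, " arm")
    if (sum(x) == 0) stop("degenerate table: all-zero ", arm, " arm")
  }
  check_triple(counts_case, "case")
  check_triple(counts_control, "control")
  c(a = 2 * counts_case[3] + counts_case[2],
    b = 2 * counts_case[1] + counts_case[2],
    c = 2 * counts_control[3] + counts_control[2],
    d = 2 * counts_control[1] + counts_control[2])
}

# One-row effect-estimate data frame; effects tables are rbinds of these.
effect_estimate <- function(log_or, se, contrast, study_id = NA_character_,
                            year = NA_integer_, corrected = FALSE) {
  stopifnot(is.finite(se), se > 0)
  data.frame(study_id = study_id, year = year, log_or = log_or, se = se,
             contrast = contrast, corrected = corrected,
             stringsAsFactors = FALSE)
}

#' Odds ratio and log-OR standard error from a 2x2 table
#'
#' Computes OR = ad/(bc), its natural log and the Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`.  If any cell is zero the Haldane-Anscombe
#' continuity correction adds 0.5 to all four cells first (`corrected` flag
#' set).
#'
#' @param a,b,c,d Cell counts: exposed/unexposed cases, exposed/unexposed
#'   controls.
#' @param correction `"haldane"` (default) or `"none"`; with `"none"` a zero
#'   cell is a degenerate-table error.
#' @param contrast Label stored on the estimate (e.g. `"allele"`).
#' @param study_id,year Provenance carried through to pooling.
#' @return One-row data frame: `study_id`, `year`, `log_or`, `se`,
#'   `contrast`, `corrected`.
#' @examples
#' odds_ratio_2x2(20, 80, 10, 90)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, correction = c("haldane", "none"),
                           contrast = "allele", study_id = NA_character_,
                           year = NA_integer_) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("invalid 2x2 cell counts")
  if (a + b == 0 || c + d == 0) stop("degenerate table: empty arm")
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction == "none")
      stop("degenerate table: zero cell with correction disabled")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  if (!is.finite(log_or) || !is.finite(se))
    stop("degenerate table: non-finite estimate")
  effect_estimate(log_or, se, contrast, study_id, year, corrected)
}

#' Per-genotype odds ratios against the common-homozygote reference
#'
#' Forms the two 2x2 sub-tables (heterozygote vs common homozygote and rare
#' homozygote vs common homozygote) and estimates each log OR and SE as in
#' [odds_ratio_2x2()].  The two estimates share the reference cells; the
#' induced correlation is handled downstream by bootstrapping over studies
#' rather than analytically.
#'
#' @param counts_case,counts_control Genotype triples (common hom, het, rare
#'   hom).
#' @param correction Continuity-correction rule, per sub-table.
#' @param study_id,year Provenance.
#' @return List with `or1` (het vs common hom) and `or2` (rare hom vs common
#'   hom), each a one-row effect data frame.
#' @examples
#' genotype_ors(c(50, 100, 50), c(100, 80, 20))
#' @export
genotype_ors <- function(counts_case, counts_control,
                         correction = c("haldane", "none"),
                         study_id = NA_character_, year = NA_integer_) {
  correction <- match.arg(correction)
  if (counts_case[1] == 0 || counts_control[1] == 0)
    stop("degenerate table: empty common-homozygote reference genotype")
  or1 <- odds_ratio_2x2(counts_case[2], counts_case[1],
                        counts_control[2], counts_control[1],
                        correction = correction,
                        contrast = "het-vs-common-hom",
                        study_id = study_id, year = year)
  or2 <- odds_ratio_2x2(counts_case[3], counts_case[1],
                        counts_control[3], counts_control[1],
                        correction = correction,
                        contrast = "rare-hom-vs-common-hom",
                        study_id = study_id, year = year)
  list(or1 = or1, or2 = or2)
}

#' Hardy-Weinberg equilibrium test on genotype counts
#'
#' The chi-square method compares observed genotype counts with the expected
#' counts (n p^2, 2 n p q, n q^2) at the observed allele frequency, on one
#' degree of freedom, without continuity correction.  The exact method
#' conditions on the allele counts and enumerates all heterozygote counts of
#' the correct parity; the two-sided p-value is the cumulative probability of
#' tables as or less probable than the observed one.
#'
#' @param counts Genotype triple (common hom, het, rare hom), usually the
#'   control arm.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return List: `p_value`, `statistic` (chi-square only), `method`,
#'   `monomorphic` (TRUE when one allele is absent; then `p_value = 1` with a
#'   warning).
#' @examples
#' hwe_test(c(30, 40, 30))$statistic  # 4.0
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0))
    stop("invalid genotype triple")
  n <- sum(counts)
  if (n <= 0) stop("empty sample")
  n_minor <- 2 * counts[3] + counts[2]
  n_major <- 2 * counts[1] + counts[2]
  if (n_minor == 0 || n_major == 0) {
    warning("monomorphic sample: HWE test degenerate, p = 1")
    return(list(p_value = 1, statistic = NA_real_, method = method,
                monomorphic = TRUE))
  }
  if (method == "chisq") {
    q <- n_minor / (2 * n)
    p <- 1 - q
    expected <- n * c(p^2, 2 * p * q, q^2)
    stat <- sum((counts - expected)^2 / expected)
    list(p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         statistic = stat, method = method, monomorphic = FALSE)
  } else {
    list(p_value = hwe_exact_p(counts), statistic = NA_real_,
         method = method, monomorphic = FALSE)
  }
}

# Conditional exact HWE p: enumerate heterozygote counts with the parity of
# the minor-allele count, compute each table's conditional probability via
# log factorials, and sum the probabilities <= that of the observed table.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_minor <- 2 * counts[3] + counts[2]
  het_obs <- counts[2]
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  log_prob <- vapply(hets, function(h) {
    n_rare <- (n_minor - h) / 2
    n_comm <- n - n_rare - h
    lfactorial(n) - lfactorial(n_comm) - lfactorial(h) - lfactorial(n_rare) +
      h * log(2)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[hets == het_obs]
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

#' Per-study effect estimates from a catalogue
#'
#' Converts each study record to a log odds ratio with standard error.
#' Studies with genotype counts use the minor-allele 2x2 contrast (the
#' default preference); studies carrying only a reported OR with 95% CI use
#' `log_or = log(or)` and `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param records A `study_catalogue` or compatible data frame.
#' @param prefer_counts If `TRUE` (default), genotype counts take precedence
#'   over a reported OR when both are present.
#' @param correction Continuity-correction rule for count-based tables.
#' @return Effects data frame (one row per study) with columns `study_id`,
#'   `year`, `log_or`, `se`, `contrast`, `corrected`, plus `evidence` (minor
#'   test alleles among cases and controls; `NA` for reported-only studies)
#'   and `has_counts`.
#' @export
effects_from_records <- function(records, prefer_counts = TRUE,
                                 correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    use_counts <- has_counts(row) && (prefer_counts || !has_reported(row))
    if (use_counts) {
      tab <- allele_table_from_genotypes(
        c(row$case_hom_common, row$case_het, row$case_hom_rare),
        c(row$ctrl_hom_common, row$ctrl_het, row$ctrl_hom_rare))
      eff <- odds_ratio_2x2(tab["a"], tab["b"], tab["c"], tab["d"],
                            correction = correction, contrast = "allele",
                            study_id = row$study_id, year = row$year)
      eff$evidence <- unname(tab["a"] + tab["c"])
      eff$has_counts <- TRUE
    } else if (has_reported(row)) {
      se <- (log(row$reported_ci_high) - log(row$reported_ci_low)) /
        (2 * stats::qnorm(0.975))
      eff <- effect_estimate(log(row$reported_or), se, contrast = "reported",
                             study_id = row$study_id, year = row$year)
      eff$evidence <- NA_real_
      eff$has_counts <- FALSE
    } else {
      stop("record ", row$study_id, " has neither counts nor reported OR")
    }
    eff
  })
  do.call(rbind, rows)
}
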