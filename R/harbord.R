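#' Efficient score and score variance of a 2x2 table
#'
#' For a table with `a` exposed cases, `b` unexposed cases, `c` exposed
#' controls and `d` unexposed controls (n = a+b+c+d), the score is
#' `Z = a - (a+b)(a+c)/n` (observed minus expected exposed cases under the
#' null) and its variance `V = (a+b)(c+d)(a+c)(b+d) / (n^2 (n-1))`.
#'
#' @param a,b,c,d Cell counts; all four margins must be positive.
#' @return Named list `z`, `v`.
#' @examples
#' score_and_variance(20, 80, 10, 90)
#' @export
score_and_variance <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("invalid 2x2 cell counts")
  n <- sum(cells)
  if (n <= 1) stop("degenerate table: n <= 1")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate table: zero margin")
  z <- a - (a + b) * (a + c) / n
  v <- prod(margins) / (n^2 * (n - 1))
  list(z = z, v = v)
}

#' Harbord's modified regression test for small-study effects
#'
#' Regresses `Z_i / sqrt(V_i)` on `sqrt(V_i)` by ordinary least squares over
#' the per-study 2x2 tables; a non-zero intercept signals small-study
#' effects (funnel asymmetry) for binary-outcome meta-analyses.  The
#' two-sided p-value uses the t distribution on k-2 degrees of freedom.
#'
#' Studies without genotype counts cannot contribute a table and must be
#' excluded by the caller; the test is skipped (with reason) when fewer than
#' `min_k` tables remain.
#'
#' @param tables Matrix or data frame with columns `a`, `b`, `c`, `d`
#'   (one row per study), or a list of length-4 vectors.
#' @param min_k Minimum number of studies to run the test (default 3).
#' @param warn_k Warn when k is below this (default 10): the test is
#'   low-powered in small meta-analyses.
#' @return A `harbord_result`: `intercept`, `intercept_se`, `t_stat`,
#'   `p_value`, `k_used`, `skipped`, `reason`.
#' @examples
#' tabs <- rbind(c(20, 80, 10, 90), c(40, 160, 25, 175), c(15, 45, 12, 48))
#' harbord_test(tabs)
#' @export
harbord_test <- function(tables, min_k = 3, warn_k = 10) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  tables <- as.matrix(tables)
  k <- nrow(tables)
  if (k < min_k) {
    res <- list(intercept = NA_real_, intercept_se = NA_real_,
                t_stat = NA_real_, p_value = NA_real_, k_used = k,
                skipped = TRUE,
                reason = sprintf("only %d studies with counts (min_k = %d)", k, min_k))
    class(res) <- "harbord_result"
    return(res)
  }
  if (k < warn_k)
    warning("Harbord test on only ", k, " studies: low power")
  zv <- lapply(seq_len(k), function(i)
    score_and_variance(tables[i, 1], tables[i, 2], tables[i, 3], tables[i, 4]))
  v <- vapply(zv, `[[`, numeric(1), "v")
  z <- vapply(zv, `[[`, numeric(1), "z")
  x <- sqrt(v)
  y <- z / sqrt(v)
  if (stats::sd(x) == 0)
    stop("collinearity: identical score variances across studies")
  fit <- stats::lm(y ~ x)
  est <- summary(fit)$coefficients
  res <- list(intercept = est[1, 1], intercept_se = est[1, 2],
              t_stat = est[1, 3],
              p_value = 2 * stats::pt(-abs(est[1, 3]), df = k - 2),
              k_used = k, skipped = FALSE, reason = NA_character_)
  class(res) <- "harbord_result"
  res
}

#' @export
print.harbord_result <- function(x, ...) {
  if (x$skipped) {
    cat("Harbord test skipped:", x$reason, "\n")
  } else {
    cat(sprintf("Harbord small-study-effects test (k = %d)\n", x$k_used))
    cat(sprintf("  intercept %.4f (se %.4f), t = %.3f, p = %.4f\n",
                x$intercept, x$intercept_se, x$t_stat, x$p_value))
  }
  invisible(x)
}

# Allele 2x2 tables for the count-bearing studies of one association.
allele_tables_from_records <- function(records) {
  keep <- vapply(seq_len(nrow(records)), function(i) has_counts(records[i, ]),
                 logical(1))
  recs <- records[keep, , drop = FALSE]
  if (nrow(recs) == 0) return(matrix(numeric(0), ncol = 4,
                                     dimnames = list(NULL, c("a", "b", "c", "d"))))
  t(vapply(seq_len(nrow(recs)), function(i) {
    row <- recs[i, ]
    allele_table_from_genotypes(
      c(row$case_hom_common, row$case_het, row$case_hom_rare),
      c(row$ctrl_hom_common, row$ctrl_het, row$ctrl_hom_rare))
  }, numeric(4)))
}
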