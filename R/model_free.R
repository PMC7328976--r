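#' Pool per-genotype effects across studies
#'
#' Estimates OR1 (heterozygote vs common homozygote) and OR2 (rare
#' homozygote vs common homozygote) in every study with genotype counts and
#' pools each contrast independently by DerSimonian-Laird random effects.
#' The two contrasts share the reference cell within each study; that
#' correlation is handled empirically by the study-level bootstrap in
#' [lambda_estimate()] rather than by an analytic covariance.
#'
#' @param records Catalogue rows for one association; only count-bearing
#'   studies contribute.
#' @param correction Continuity-correction rule.
#' @return List: `pooled_log_or1`, `pooled_log_or2`, `k`, and the per-study
#'   effects tables `effects1`, `effects2`.
#' @export
pool_genotype_effects <- function(records, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  keep <- vapply(seq_len(nrow(records)), function(i) has_counts(records[i, ]),
                 logical(1))
  recs <- records[keep, , drop = FALSE]
  if (nrow(recs) < 2)
    stop("model-free analysis skipped: fewer than 2 studies with genotype counts")
  pairs <- lapply(seq_len(nrow(recs)), function(i) {
    row <- recs[i, ]
    genotype_ors(c(row$case_hom_common, row$case_het, row$case_hom_rare),
                 c(row$ctrl_hom_common, row$ctrl_het, row$ctrl_hom_rare),
                 correction = correction, study_id = row$study_id,
                 year = row$year)
  })
  effects1 <- do.call(rbind, lapply(pairs, `[[`, "or1"))
  effects2 <- do.call(rbind, lapply(pairs, `[[`, "or2"))
  list(pooled_log_or1 = pool_random_dl(effects1)$pooled_log_or,
       pooled_log_or2 = pool_random_dl(effects2)$pooled_log_or,
       k = nrow(recs), effects1 = effects1, effects2 = effects2)
}

# Re-pool a study resample and return lambda, or NA when degenerate.
lambda_from_records <- function(records, correction, floor) {
  pooled <- tryCatch(pool_genotype_effects(records, correction),
                     error = function(e) NULL)
  if (is.null(pooled) || abs(pooled$pooled_log_or2) <= floor) return(NA_real_)
  pooled$pooled_log_or1 / pooled$pooled_log_or2
}

#' Lambda (ratio of log odds ratios) with bootstrap CI
#'
#' `lambda = log(OR1) / log(OR2)` summarizes the mode of inheritance:
#' about 0 recessive, about 0.5 additive/codominant, about 1 dominant.  The
#' point estimate uses the independently pooled contrasts; the confidence
#' interval is a nonparametric percentile bootstrap over studies (resample k
#' studies with replacement, re-pool both contrasts, recompute lambda),
#' which respects the shared-reference-cell correlation empirically.
#'
#' @param records Catalogue rows for one association.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling (mandatory).
#' @param floor Minimum `|pooled log OR2|` below which lambda is undefined
#'   (default 0.05): the ratio is numerically unstable near a null OR2.
#' @param correction Continuity-correction rule.
#' @return List: `lambda`, `lambda_ci` (2.5/97.5 percentiles), `n_boot`,
#'   `n_effective` (bootstrap replicates with a defined lambda), or
#'   `undetermined = TRUE` with a `reason` when the floor is violated.
#' @export
lambda_estimate <- function(records, n_boot = 2000, seed,
                            floor = 0.05, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  if (missing(seed) || is.na(seed)) stop("seed is mandatory for the bootstrap")
  pooled <- pool_genotype_effects(records, correction)
  if (abs(pooled$pooled_log_or2) <= floor)
    return(list(lambda = NA_real_, lambda_ci = c(NA_real_, NA_real_),
                undetermined = TRUE,
                reason = sprintf("|pooled log OR2| = %.4f below floor %.3f",
                                 abs(pooled$pooled_log_or2), floor)))
  lambda <- pooled$pooled_log_or1 / pooled$pooled_log_or2
  keep <- vapply(seq_len(nrow(records)), function(i) has_counts(records[i, ]),
                 logical(1))
  recs <- records[keep, , drop = FALSE]
  k <- nrow(recs)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      lambda_from_records(recs[idx, , drop = FALSE], correction, floor)
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  ci <- if (length(boot) >= 10) {
    unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  } else c(NA_real_, NA_real_)
  list(lambda = lambda, lambda_ci = ci, n_boot = n_boot,
       n_effective = length(boot), undetermined = FALSE)
}

# Evaluate an expression under a local RNG seed, restoring global state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Classify the mode of inheritance from lambda
#'
#' Band rules on the bootstrap CI: recessive when the CI lies within
#' (-0.25, 0.25), additive/codominant within (0.25, 0.75), dominant within
#' (0.75, 1.25), beyond-range when the CI excludes the whole interval
#' `[0, 1]`, otherwise undetermined.  The canonical points 0, 0.5 and 1 are
#' the recessive, multiplicative and dominant modes; the +/-0.25 bands are a
#' reporting convention, since lambda is a continuous parameter.
#'
#' @param lambda Point estimate.
#' @param lambda_ci Length-2 CI.
#' @return One of `"recessive"`, `"additive-codominant"`, `"dominant"`,
#'   `"beyond-range"`, `"undetermined"`.
#' @export
classify_model <- function(lambda, lambda_ci) {
  if (!is.finite(lambda) || any(!is.finite(lambda_ci))) return("undetermined")
  lo <- lambda_ci[1]; hi <- lambda_ci[2]
  within <- function(l, u) lo > l && hi < u
  if (within(-0.25, 0.25)) "recessive"
  else if (within(0.25, 0.75)) "additive-codominant"
  else if (within(0.75, 1.25)) "dominant"
  else if (hi < 0 || lo > 1) "beyond-range"
  else "undetermined"
}

#' Genetic model-free analysis of one association
#'
#' Convenience wrapper chaining [pool_genotype_effects()],
#' [lambda_estimate()] and [classify_model()].
#'
#' @inheritParams lambda_estimate
#' @return A `genetic_model_estimate`: `pooled_log_or1`, `pooled_log_or2`,
#'   `lambda`, `lambda_ci`, `model_class`, `k`.
#' @export
model_free_analysis <- function(records, n_boot = 2000, seed, floor = 0.05,
                                correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  pooled <- pool_genotype_effects(records, correction)
  lam <- lambda_estimate(records, n_boot = n_boot, seed = seed, floor = floor,
                         correction = correction)
  cls <- if (isTRUE(lam$undetermined)) "undetermined"
  else classify_model(lam$lambda, lam$lambda_ci)
  res <- list(pooled_log_or1 = pooled$pooled_log_or1,
              pooled_log_or2 = pooled$pooled_log_or2,
              lambda = lam$lambda, lambda_ci = lam$lambda_ci,
              model_class = cls, k = pooled$k,
              reason = if (isTRUE(lam$undetermined)) lam$reason else NA_character_)
  class(res) <- "genetic_model_estimate"
  res
}

#' @export
print.genetic_model_estimate <- function(x, ...) {
  cat(sprintf("model-free analysis over %d studies\n", x$k))
  cat(sprintf("  OR1 %.3f, OR2 %.3f\n", exp(x$pooled_log_or1),
              exp(x$pooled_log_or2)))
  if (is.finite(x$lambda))
    cat(sprintf("  lambda %.3f (95%% CI %.3f-%.3f): %s\n", x$lambda,
                x$lambda_ci[1], x$lambda_ci[2], x$model_class))
  else cat("  lambda undetermined:", x$reason, "\n")
  invisible(x)
}
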