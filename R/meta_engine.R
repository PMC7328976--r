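# effects: data.frame with columns log_or and se (se > 0, finite).
check_effects <- function(effects, min_k = 1) {
  if (is.null(effects) || nrow(effects) == 0) stop("no effect estimates")
  if (nrow(effects) < min_k)
    stop("at least ", min_k, " studies required, got ", nrow(effects))
  if (any(!is.finite(effects$log_or)) || any(!is.finite(effects$se)) ||
      any(effects$se <= 0))
    stop("effects must have finite log_or and positive finite se")
  invisible(effects)
}

meta_result <- function(k, pooled_log_or, pooled_se, p_value, q_stat, q_p,
                        i_squared_pct, tau2, model, evidence_amount = NA_real_) {
  z975 <- stats::qnorm(0.975)
  res <- list(k = k,
              pooled_log_or = pooled_log_or,
              pooled_se = pooled_se,
              or_pooled = exp(pooled_log_or),
              ci_low = exp(pooled_log_or - z975 * pooled_se),
              ci_high = exp(pooled_log_or + z975 * pooled_se),
              p_value = p_value,
              q_stat = q_stat, q_p = q_p,
              i_squared_pct = i_squared_pct, tau2 = tau2,
              model = model, evidence_amount = evidence_amount)
  class(res) <- "meta_result"
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect meta-analysis of %d studies\n", x$model, x$k))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or_pooled, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  Q = %.3f (p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
              x$q_stat, x$q_p, x$i_squared_pct, x$tau2))
  if (!is.na(x$evidence_amount))
    cat(sprintf("  evidence amount: %d test alleles\n",
                as.integer(x$evidence_amount)))
  invisible(x)
}

total_evidence <- function(effects) {
  if (is.null(effects$evidence) || all(is.na(effects$evidence))) return(NA_real_)
  sum(effects$evidence, na.rm = TRUE)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pools per-study log odds ratios with weights `1/se^2`.  With a single
#' study the result is that study's estimate; heterogeneity statistics are
#' reported as zero/undefined.
#'
#' @param effects Effects data frame (see [effects_from_records()]); only
#'   `log_or` and `se` are required.
#' @return A `meta_result`: pooled OR, 95% CI, two-sided normal p, Cochran's
#'   Q and its p, I-squared (percent), tau-squared, model label, and the
#'   evidence-amount tally when the effects carry an `evidence` column.
#' @examples
#' eff <- data.frame(log_or = c(0, 0.6931), se = c(0.1, 0.1))
#' pool_fixed(eff)
#' @export
pool_fixed <- function(effects) {
  check_effects(effects)
  k <- nrow(effects)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  p <- 2 * stats::pnorm(-abs(pooled / se))
  if (k >= 2) {
    het <- heterogeneity(effects)
  } else {
    het <- list(q_stat = 0, q_p = NA_real_, i_squared_pct = 0, tau2 = 0)
  }
  meta_result(k, pooled, se, p, het$q_stat, het$q_p, het$i_squared_pct,
              het$tau2, "fixed", total_evidence(effects))
}

#' Heterogeneity statistics
#'
#' Cochran's Q with fixed-effect weights, its chi-square p on k-1 degrees of
#' freedom, I-squared = max(0, (Q - (k-1))/Q) x 100, and the
#' DerSimonian-Laird moment estimator
#' tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w))).
#'
#' @inheritParams pool_fixed
#' @return List: `q_stat`, `q_p`, `i_squared_pct`, `tau2`.
#' @examples
#' heterogeneity(data.frame(log_or = c(0, 0.6931), se = c(0.1, 0.1)))
#' @export
heterogeneity <- function(effects) {
  check_effects(effects, min_k = 2)
  k <- nrow(effects)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  q <- sum(w * (effects$log_or - pooled)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
  list(q_stat = q, q_p = q_p, i_squared_pct = i2, tau2 = tau2)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance pooling with weights `1/(se^2 + tau2)`, tau-squared from
#' [heterogeneity()].  When tau2 = 0 the result coincides with
#' [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @return A `meta_result` with `model = "random"`.
#' @export
pool_random_dl <- function(effects) {
  check_effects(effects, min_k = 2)
  het <- heterogeneity(effects)
  w <- 1 / (effects$se^2 + het$tau2)
  pooled <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  p <- 2 * stats::pnorm(-abs(pooled / se))
  meta_result(nrow(effects), pooled, se, p, het$q_stat, het$q_p,
              het$i_squared_pct, het$tau2, "random", total_evidence(effects))
}

#' Choose the pooling model from heterogeneity
#'
#' Default policy: random effects when I-squared exceeds `i2_threshold` or
#' the Q-test p falls below `qp_threshold`, else fixed effect.  The policy is
#' configuration, recorded in the run manifest.
#'
#' @param het Heterogeneity list from [heterogeneity()].
#' @param i2_threshold I-squared percent cutpoint (default 50).
#' @param qp_threshold Q-test p cutpoint (default 0.10).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het, i2_threshold = 50, qp_threshold = 0.10) {
  if (het$i_squared_pct > i2_threshold ||
      (!is.na(het$q_p) && het$q_p < qp_threshold)) "random" else "fixed"
}

# Pool under the configured policy; k = 1 falls back to fixed.
pool_auto <- function(effects, i2_threshold = 50, qp_threshold = 0.10) {
  if (nrow(effects) < 2) return(pool_fixed(effects))
  het <- heterogeneity(effects)
  if (select_model(het, i2_threshold, qp_threshold) == "random")
    pool_random_dl(effects)
  else pool_fixed(effects)
}

# Order used for "first published" and cumulative accumulation.
publication_order <- function(records) {
  order(records$year, records$author, records$study_id)
}

#' Sensitivity suite for one association
#'
#' Recomputes the pooled result (i) leaving each study out in turn, (ii)
#' dropping the earliest-published study (ties broken by author, then
#' study id), and (iii) dropping studies whose control-arm HWE p falls below
#' `hwe_threshold`.  The association is `stable` when every variant of the
#' pooled OR keeps the full-analysis direction and its CI excludes 1
#' whenever the full CI excludes 1.
#'
#' @param records Catalogue rows for one variant-cancer association (k >= 2).
#' @param hwe_threshold Control-arm HWE exclusion p (default 0.05).
#' @param prefer_counts,correction Passed to [effects_from_records()].
#' @param i2_threshold,qp_threshold Model-selection policy.
#' @return A `sensitivity_report`: `loo_or_range`, `drop_first_or`,
#'   `drop_hwe_or`, `stable`, `skipped`, and a `details` data frame of every
#'   re-pooled variant.
#' @export
sensitivity_suite <- function(records, hwe_threshold = 0.05,
                              prefer_counts = TRUE,
                              correction = c("haldane", "none"),
                              i2_threshold = 50, qp_threshold = 0.10) {
  correction <- match.arg(correction)
  if (nrow(records) < 2) stop("sensitivity suite requires k >= 2")
  repool <- function(recs) {
    eff <- effects_from_records(recs, prefer_counts, correction)
    pool_auto(eff, i2_threshold, qp_threshold)
  }
  full <- repool(records)
  variants <- list()
  for (i in seq_len(nrow(records)))
    variants[[paste0("loo:", records$study_id[i])]] <-
      repool(records[-i, , drop = FALSE])
  first <- publication_order(records)[1]
  variants[["drop_first"]] <- repool(records[-first, , drop = FALSE])
  hwe_p <- if ("hwe_p" %in% names(records)) records$hwe_p else rep(NA_real_, nrow(records))
  violators <- which(!is.na(hwe_p) & hwe_p < hwe_threshold)
  skipped <- FALSE
  if (length(violators) == 0) {
    variants[["drop_hwe"]] <- full
  } else if (nrow(records) - length(violators) >= 1) {
    variants[["drop_hwe"]] <- repool(records[-violators, , drop = FALSE])
  } else {
    skipped <- TRUE
  }
  ors <- vapply(variants, function(m) m$or_pooled, numeric(1))
  full_sig <- full$ci_low > 1 || full$ci_high < 1
  keeps <- vapply(variants, function(m) {
    same_dir <- sign(m$pooled_log_or) == sign(full$pooled_log_or) ||
      full$pooled_log_or == 0
    sig_kept <- !full_sig || (m$ci_low > 1 || m$ci_high < 1)
    same_dir && sig_kept
  }, logical(1))
  loo <- ors[grepl("^loo:", names(ors))]
  res <- list(full = full,
              loo_or_range = range(loo),
              drop_first_or = unname(ors[["drop_first"]]),
              drop_hwe_or = if ("drop_hwe" %in% names(ors)) unname(ors[["drop_hwe"]]) else NA_real_,
              stable = all(keeps),
              skipped = skipped,
              details = data.frame(variant = names(ors), or = unname(ors),
                                   keeps = unname(keeps),
                                   stringsAsFactors = FALSE))
  class(res) <- "sensitivity_report"
  res
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity suite: leave-one-out OR in [%.3f, %.3f]\n",
              x$loo_or_range[1], x$loo_or_range[2]))
  cat(sprintf("  drop first published: OR %.3f; drop HWE violators: OR %s\n",
              x$drop_first_or,
              ifelse(is.na(x$drop_hwe_or), "skipped", sprintf("%.3f", x$drop_hwe_or))))
  cat(sprintf("  stable: %s\n", x$stable))
  invisible(x)
}

#' Cumulative meta-analysis in publication order
#'
#' Pools the first j studies for j = 1..k in (year, author, study id) order,
#' showing how evidence accrues over publication time.
#'
#' @param records Catalogue rows for one association.
#' @param model `"fixed"` (default), `"random"`, or `"auto"` (policy-based).
#' @param prefer_counts,correction Passed to [effects_from_records()].
#' @return List of `meta_result`, one per accumulation step; the last element
#'   equals the full pooled result under the same model.
#' @export
cumulative_by_year <- function(records, model = c("fixed", "random", "auto"),
                               prefer_counts = TRUE,
                               correction = c("haldane", "none")) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  if (nrow(records) < 1) stop("no studies")
  records <- records[publication_order(records), , drop = FALSE]
  effects <- effects_from_records(records, prefer_counts, correction)
  lapply(seq_len(nrow(effects)), function(j) {
    sub <- effects[seq_len(j), , drop = FALSE]
    if (j == 1 || model == "fixed") pool_fixed(sub)
    else if (model == "random") pool_random_dl(sub)
    else pool_auto(sub)
  })
}

#' Subgroup meta-analysis
#'
#' Independent pooled results per stratum of a grouping column.
#'
#' @param records Catalogue rows for one association.
#' @param key Stratifying column: `"ethnicity"` or `"design"`.
#' @param ... Passed to [effects_from_records()] and the model policy.
#' @return Named list of `meta_result`, one per stratum; strata with a single
#'   study carry attribute `single_study = TRUE`.
#' @export
subgroup_meta <- function(records, key = c("ethnicity", "design"), ...) {
  key <- match.arg(key)
  if (any(is.na(records[[key]]))) stop("key '", key, "' missing on some records")
  strata <- split(seq_len(nrow(records)), records[[key]], drop = TRUE)
  out <- lapply(strata, function(idx) {
    eff <- effects_from_records(records[idx, , drop = FALSE], ...)
    m <- pool_auto(eff)
    if (length(idx) == 1) attr(m, "single_study") <- TRUE
    m
  })
  out
}

#' Random-effects meta-regression on one covariate
#'
#' Weighted least squares of the per-study log OR on a covariate with
#' weights `1/(se^2 + tau2)`, tau-squared taken from the intercept-only
#' DerSimonian-Laird moment estimator; the slope p-value is normal-theory
#' (known-variance weights).
#'
#' @param effects Effects data frame.
#' @param covariate Numeric vector, one value per study.
#' @return List: `slope`, `slope_se`, `p`, `intercept`, `tau2`.
#' @export
meta_regression <- function(effects, covariate) {
  check_effects(effects, min_k = 3)
  if (length(covariate) != nrow(effects))
    stop("covariate length must match number of studies")
  if (stats::var(covariate) == 0)
    stop("collinearity: covariate is constant across studies")
  tau2 <- heterogeneity(effects)$tau2
  w <- 1 / (effects$se^2 + tau2)
  x <- cbind(1, covariate)
  xtwx <- crossprod(x, w * x)
  beta <- solve(xtwx, crossprod(x, w * effects$log_or))
  cov_beta <- solve(xtwx)
  slope <- beta[2]
  slope_se <- sqrt(cov_beta[2, 2])
  list(slope = slope, slope_se = slope_se,
       p = 2 * stats::pnorm(-abs(slope / slope_se)),
       intercept = beta[1], tau2 = tau2)
}
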