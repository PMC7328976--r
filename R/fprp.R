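#' FPRP evidence categories
#'
#' Cutpoints for the false-positive report probability: `< 0.05` strong,
#' `0.05-0.20` (inclusive on both ends) moderate, `> 0.20` weak evidence of a
#' true association.
#'
#' @return Character vector of the three category labels.
#' @export
fprp_categories <- function() c("<0.05", "0.05-0.20", ">0.20")

fprp_categorize <- function(fprp) {
  if (fprp < 0.05) "<0.05" else if (fprp <= 0.20) "0.05-0.20" else ">0.20"
}

#' Power of the two-sided normal test at a target effect
#'
#' With `z*` the upper alpha/2 normal quantile and `delta = |target_log_or| /
#' se`, power = 1 - pnorm(z* - delta) + pnorm(-z* - delta): the probability
#' of declaring significance at level `alpha` when the true log OR equals the
#' target, given the estimate's standard error.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param se Standard error of the log OR estimate.
#' @param target_log_or Log odds ratio deemed worth detecting; the sign is
#'   irrelevant.
#' @return Power in (0, 1].
#' @examples
#' power_at(0.05, se = 0.1, target_log_or = log(1.5))
#' @export
power_at <- function(alpha, se, target_log_or) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.finite(se) || se <= 0) stop("se must be positive and finite")
  if (!is.finite(target_log_or)) stop("target_log_or must be finite")
  # upper-tail form keeps precision for the very small observed p-values
  # typical of GWAS-era pooled associations
  z_star <- stats::qnorm(alpha / 2, lower.tail = FALSE)
  delta <- abs(target_log_or) / se
  1 - stats::pnorm(z_star - delta) + stats::pnorm(-z_star - delta)
}

#' False-positive report probability
#'
#' `FPRP = alpha (1 - prior) / (alpha (1 - prior) + power x prior)`: the
#' posterior probability that a statistically significant finding is a false
#' positive, given the observed significance level, the power to detect a
#' target effect, and the prior probability of a true association.
#'
#' @param alpha Observed two-sided p-value, used as the significance level.
#' @param power Power at the target effect size, from [power_at()].
#' @param prior Prior probability of a true association, in (0, 1).
#' @return FPRP in (0, 1).
#' @examples
#' fprp_value(0.05, power = 0.9, prior = 0.05)
#' @export
fprp_value <- function(alpha, power, prior) {
  if (!is.finite(prior) || prior <= 0 || prior >= 1)
    stop("prior must lie strictly in (0, 1)")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!is.finite(power) || power <= 0 || power > 1) stop("power must lie in (0, 1]")
  alpha * (1 - prior) / (alpha * (1 - prior) + power * prior)
}

#' FPRP profile of a pooled association
#'
#' Evaluates the false-positive report probability over a grid of priors,
#' using the pooled result's observed two-sided p as the significance level
#' and its standard error for the power calculation.  Protective pooled
#' effects (OR < 1) use the reciprocal target, which is the same log-scale
#' magnitude.
#'
#' @param meta A `meta_result`, or a list with `p_value` and either
#'   `pooled_se` or `ci_low`/`ci_high` (the SE is then recovered as
#'   `(log(ci_high) - log(ci_low)) / (2 x 1.959964)`).
#' @param priors Prior-probability grid (default 0.25, 0.1, 0.05, 0.01,
#'   0.001).
#' @param target_or Odds ratio worth detecting (default 1.5).
#' @param headline_prior Prior at which the evidence category is assigned
#'   (default 0.05).
#' @return An `fprp_result`: `observed_p`, `se_log_or`, `target_or`, `power`,
#'   `priors`, `fprp_values`, `headline_prior`, `headline_fprp`, `category`,
#'   `degenerate`.
#' @examples
#' eff <- data.frame(log_or = c(0.25, 0.3, 0.2), se = c(0.05, 0.08, 0.06))
#' fprp_for_association(pool_fixed(eff))
#' @export
fprp_for_association <- function(meta, priors = c(0.25, 0.1, 0.05, 0.01, 0.001),
                                 target_or = 1.5, headline_prior = 0.05) {
  if (!is.finite(target_or) || target_or <= 1)
    stop("target_or must exceed 1 (the protective side uses its reciprocal)")
  if (!headline_prior %in% priors) priors <- sort(c(priors, headline_prior),
                                                  decreasing = TRUE)
  p <- meta$p_value
  se <- meta$pooled_se
  if (is.null(se) || is.na(se)) {
    if (is.null(meta$ci_low) || is.null(meta$ci_high))
      stop("meta must carry pooled_se or a CI to recover it from")
    se <- (log(meta$ci_high) - log(meta$ci_low)) / (2 * stats::qnorm(0.975))
  }
  if (!is.finite(p) || p <= 0) stop("meta p-value must be finite and positive")
  degenerate <- p >= 1
  if (degenerate) {
    res <- list(observed_p = p, se_log_or = se, target_or = target_or,
                power = NA_real_, priors = priors,
                fprp_values = rep(NA_real_, length(priors)),
                headline_prior = headline_prior, headline_fprp = NA_real_,
                category = ">0.20", degenerate = TRUE)
    class(res) <- "fprp_result"
    return(res)
  }
  pw <- power_at(p, se, log(target_or))
  vals <- vapply(priors, function(pi) fprp_value(p, pw, pi), numeric(1))
  headline <- vals[match(headline_prior, priors)]
  res <- list(observed_p = p, se_log_or = se, target_or = target_or,
              power = pw, priors = priors, fprp_values = vals,
              headline_prior = headline_prior, headline_fprp = headline,
              category = fprp_categorize(headline), degenerate = FALSE)
  class(res) <- "fprp_result"
  res
}

#' @export
print.fprp_result <- function(x, ...) {
  cat(sprintf("FPRP at observed p = %.3g (power %.3f at OR %.2f)\n",
              x$observed_p, x$power, x$target_or))
  print(data.frame(prior = x$priors, fprp = x$fprp_values))
  cat(sprintf("  category at prior %.3g: %s\n", x$headline_prior, x$category))
  invisible(x)
}
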