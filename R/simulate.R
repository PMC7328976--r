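#' Simulation configuration for synthetic study catalogues
#'
#' Defines the data-generating process the analysis assumes: control
#' genotypes in Hardy-Weinberg proportions at a given minor allele frequency;
#' per-genotype disease odds (1, OR1, OR2) with `OR1 = OR2^lambda`; a
#' study-level random effect of variance `tau2` on the log OR2 scale; and an
#' optional p-value-dependent publication-selection mechanism.
#'
#' Defaults emulate a typical common-variant cancer-association literature:
#' MAF 0.3, a multiplicative (lambda = 0.5) per-allele odds ratio of 1.3
#' (`or2 = 1.69`), no between-study heterogeneity, and per-arm sample sizes
#' drawn uniformly between 100 and 1000 subjects.
#'
#' @param n_studies Number of studies (>= 1).
#' @param maf Minor allele frequency in controls, in (0, 0.5].
#' @param or2 Rare-homozygote vs common-homozygote odds ratio (> 0).
#' @param lambda Mode-of-inheritance parameter: `OR1 = OR2^lambda` (0
#'   recessive, 0.5 multiplicative, 1 dominant).
#' @param tau2 Between-study variance of the log OR2 (>= 0).
#' @param n_cases,n_controls Fixed per-arm sample sizes, or `NULL` to draw
#'   them uniformly from `n_range`.
#' @param n_range Integer range for sampled per-arm sizes.
#' @param hwe_in_controls If `FALSE`, control genotypes are perturbed with an
#'   inbreeding coefficient of 0.1 (heterozygote deficit), emulating
#'   genotyping problems.
#' @param selection `NULL` for none, `TRUE` for the default rule (publish
#'   with probability 1 when the study's allele-OR p < 0.05, else 0.25), or
#'   a list with `p_threshold` and `prob_otherwise`.
#' @param seed Mandatory integer seed; per-study substreams are derived from
#'   it (see [simulate_study()]).
#' @param variant,cancer,ethnicity Labels stamped on the records.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_studies, maf = 0.3, or2 = 1.69, lambda = 0.5,
                       tau2 = 0, n_cases = NULL, n_controls = NULL,
                       n_range = c(100L, 1000L), hwe_in_controls = TRUE,
                       selection = NULL, seed,
                       variant = "rsSIM0001", cancer = "prostate",
                       ethnicity = "Caucasian") {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory")
  if (n_studies < 1) stop("n_studies must be >= 1")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (or2 <= 0) stop("or2 must be positive")
  if (tau2 < 0) stop("tau2 must be non-negative")
  if (!is.null(n_cases) && n_cases < 1) stop("n_cases must be >= 1")
  if (!is.null(n_controls) && n_controls < 1) stop("n_controls must be >= 1")
  if (isTRUE(selection)) selection <- list(p_threshold = 0.05,
                                           prob_otherwise = 0.25)
  if (!is.null(selection) &&
      (is.null(selection$p_threshold) || is.null(selection$prob_otherwise)))
    stop("selection must provide p_threshold and prob_otherwise")
  cfg <- list(n_studies = as.integer(n_studies), maf = maf, or2 = or2,
              lambda = lambda, tau2 = tau2, n_cases = n_cases,
              n_controls = n_controls, n_range = as.integer(n_range),
              hwe_in_controls = hwe_in_controls, selection = selection,
              seed = as.integer(seed), variant = variant, cancer = cancer,
              ethnicity = ethnicity)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-study substream seed: studies can be appended to a
# catalogue without reshuffling earlier ones.
study_seed <- function(seed, study_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(study_index) * 16807) %%
               2147483647)
}

# Control genotype probabilities (common hom, het, rare hom).
control_genotype_probs <- function(maf, hwe = TRUE, f = 0.1) {
  q <- maf; p <- 1 - maf
  if (hwe) c(p^2, 2 * p * q, q^2)
  else c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
}

# Case genotype probabilities: odds-weight the control distribution by the
# per-genotype disease odds (1, OR1, OR2) and renormalize (logistic disease
# model, rare-disease interpretation), so the generating ORs are exactly the
# estimators' targets.
case_genotype_probs <- function(ctrl_probs, or1, or2) {
  w <- ctrl_probs * c(1, or1, or2)
  w / sum(w)
}

#' Simulate one case-control study
#'
#' Deterministic given `(config$seed, study_index)`: each study uses its own
#' RNG substream, so catalogues are extensible without reshuffling history.
#' Control genotype probabilities follow HWE at the configured MAF; the
#' study's log OR2 is drawn from N(log or2, tau2) and OR1 = exp(lambda x
#' log OR2); case probabilities re-weight the control distribution by the
#' genotype odds; counts are multinomial.
#'
#' @param config A [sim_config()].
#' @param study_index 1-based study index.
#' @return One-row study-record data frame (catalogue schema), with
#'   attributes `true_log_or2` and `true_log_or1`.
#' @export
simulate_study <- function(config, study_index) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(study_seed(config$seed, study_index), {
    log_or2 <- stats::rnorm(1, log(config$or2), sqrt(config$tau2))
    or2 <- exp(log_or2)
    or1 <- exp(config$lambda * log_or2)
    ctrl_p <- control_genotype_probs(config$maf, config$hwe_in_controls)
    case_p <- case_genotype_probs(ctrl_p, or1, or2)
    n_ca <- if (is.null(config$n_cases))
      sample(config$n_range[1]:config$n_range[2], 1) else config$n_cases
    n_co <- if (is.null(config$n_controls))
      sample(config$n_range[1]:config$n_range[2], 1) else config$n_controls
    case_counts <- as.vector(stats::rmultinom(1, n_ca, case_p))
    ctrl_counts <- as.vector(stats::rmultinom(1, n_co, ctrl_p))
    rec <- data.frame(
      study_id = sprintf("SIM%04d", study_index),
      author = sprintf("Sim%04d", study_index),
      year = 1998L + (study_index - 1L) %% 20L,
      cancer = config$cancer, variant = config$variant,
      ethnicity = config$ethnicity, design = "case-control",
      case_hom_common = case_counts[1], case_het = case_counts[2],
      case_hom_rare = case_counts[3],
      ctrl_hom_common = ctrl_counts[1], ctrl_het = ctrl_counts[2],
      ctrl_hom_rare = ctrl_counts[3],
      reported_or = NA_real_, reported_ci_low = NA_real_,
      reported_ci_high = NA_real_, gwas_replicated = FALSE,
      stringsAsFactors = FALSE)
    attr(rec, "true_log_or2") <- log_or2
    attr(rec, "true_log_or1") <- config$lambda * log_or2
    rec
  })
}

# Publication probability under the selection rule.  The one-sided p-value
# in the risk direction is used: publication bias is directional (positive
# findings are the publishable ones), and a two-sided rule would thin both
# tails symmetrically, producing no funnel asymmetry at all.
study_published <- function(rec, selection, seed, study_index) {
  eff <- effects_from_records(rec)
  p <- stats::pnorm(eff$log_or / eff$se, lower.tail = FALSE)
  withr_seed(study_seed(seed, study_index) + 1L, {
    keep_prob <- if (p < selection$p_threshold) 1 else selection$prob_otherwise
    stats::runif(1) <= keep_prob
  })
}

#' Simulate a study catalogue
#'
#' Generates `n_studies` independent studies under a [sim_config()],
#' optionally thins them by the publication-selection rule, validates the
#' result as a catalogue and attaches a truth sidecar with the generating
#' parameters and per-study true effects (retrievable with
#' [catalogue_truth()]).
#'
#' @param config A [sim_config()].
#' @return A `study_catalogue`; attribute `truth` carries the generating
#'   parameters, per-study true log ORs and the published/selected flags.
#' @examples
#' cat10 <- simulate_catalogue(sim_config(n_studies = 10, seed = 42))
#' pool_fixed(effects_from_records(cat10))
#' @export
simulate_catalogue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  studies <- lapply(seq_len(config$n_studies),
                    function(i) simulate_study(config, i))
  published <- rep(TRUE, config$n_studies)
  if (!is.null(config$selection)) {
    published <- vapply(seq_len(config$n_studies), function(i)
      study_published(studies[[i]], config$selection, config$seed, i),
      logical(1))
    if (!any(published))
      stop("publication selection removed every study; relax the rule or add studies")
  }
  records <- do.call(rbind, studies[published])
  out <- as_study_catalogue(records)
  stopifnot(nrow(catalogue_rejects(out)) == 0)
  attr(out, "truth") <- list(
    config = unclass(config),
    true_log_or2 = vapply(studies, attr, numeric(1), "true_log_or2"),
    true_log_or1 = vapply(studies, attr, numeric(1), "true_log_or1"),
    published = published)
  out
}

#' Truth sidecar of a simulated catalogue
#'
#' @param catalogue Output of [simulate_catalogue()].
#' @return List with the generating config, per-study true log ORs and the
#'   publication flags.
#' @export
catalogue_truth <- function(catalogue) attr(catalogue, "truth")

#' Write a simulated catalogue with its truth sidecar
#'
#' Writes the catalogue TSV (same schema as [read_catalogue()]) and a JSON
#' sidecar of the generating parameters.
#'
#' @param catalogue Output of [simulate_catalogue()].
#' @param path Catalogue output path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulated_catalogue <- function(catalogue, path) {
  write_catalogue(catalogue, path)
  truth <- catalogue_truth(catalogue)
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
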