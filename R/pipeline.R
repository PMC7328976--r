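#' Run configuration
#'
#' All tunable analysis settings, fully serialized into the run manifest by
#' [write_results()].
#'
#' @param i2_threshold,qp_threshold Model-selection policy: random effects
#'   when I-squared exceeds `i2_threshold` (percent) or the Q-test p falls
#'   below `qp_threshold`.
#' @param hwe_threshold Control-arm HWE exclusion p for the sensitivity
#'   suite.
#' @param correction Continuity-correction rule for 2x2 tables.
#' @param prefer_counts Prefer genotype counts over reported ORs when both
#'   are present.
#' @param fprp_priors,fprp_target_or,fprp_headline_prior FPRP settings (see
#'   [fprp_for_association()]).
#' @param harbord_min_k,harbord_threshold,harbord_warn_k Harbord-test
#'   settings: minimum studies, bias-grade significance cutpoint, and the
#'   low-power warning threshold.
#' @param n_boot Bootstrap replicates for [lambda_estimate()].
#' @param seed Seed for all stochastic steps (bootstrap).
#' @return A `run_config` list.
#' @export
run_config <- function(i2_threshold = 50, qp_threshold = 0.10,
                       hwe_threshold = 0.05,
                       correction = c("haldane", "none"),
                       prefer_counts = TRUE,
                       fprp_priors = c(0.25, 0.1, 0.05, 0.01, 0.001),
                       fprp_target_or = 1.5, fprp_headline_prior = 0.05,
                       harbord_min_k = 3, harbord_threshold = 0.10,
                       harbord_warn_k = 10, n_boot = 2000, seed = 1L) {
  cfg <- list(i2_threshold = i2_threshold, qp_threshold = qp_threshold,
              hwe_threshold = hwe_threshold,
              correction = match.arg(correction),
              prefer_counts = prefer_counts, fprp_priors = fprp_priors,
              fprp_target_or = fprp_target_or,
              fprp_headline_prior = fprp_headline_prior,
              harbord_min_k = harbord_min_k,
              harbord_threshold = harbord_threshold,
              harbord_warn_k = harbord_warn_k,
              n_boot = n_boot, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Full synopsis pipeline on a study catalogue
#'
#' For each (variant, cancer) association group: per-study effects,
#' heterogeneity and model selection, pooled estimate, sensitivity suite,
#' Harbord small-study-effects test (count-bearing studies only), FPRP, and
#' Venice grading with the FPRP upgrade.  Non-significant associations are
#' reported ungraded, matching nominal-significance grading practice; no
#' multiplicity correction is applied.
#'
#' @param records A `study_catalogue` (from [read_catalogue()] or
#'   [simulate_catalogue()]).
#' @param config A [run_config()].
#' @return A `synopsis` object: `summary` (one row per association),
#'   `forest` (per-study effect table behind forest plots), `fprp_table`
#'   (one row per association x prior), `credibility` (named list of
#'   `credibility_record`), `config`, `rejects`.
#' @examples
#' cat10 <- simulate_catalogue(sim_config(n_studies = 10, or2 = 2.25, seed = 7))
#' syn <- run_synopsis(cat10)
#' syn$summary[, c("variant", "or_pooled", "p_value", "final_grade")]
#' @export
run_synopsis <- function(records, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  groups <- split(seq_len(nrow(records)),
                  paste(records$variant, records$cancer, sep = " | "),
                  drop = TRUE)
  summary_rows <- list()
  forest_rows <- list()
  fprp_rows <- list()
  credibility <- list()
  for (g in names(groups)) {
    recs <- records[groups[[g]], , drop = FALSE]
    eff <- effects_from_records(recs, config$prefer_counts, config$correction)
    meta <- pool_auto(eff, config$i2_threshold, config$qp_threshold)
    significant <- is.finite(meta$p_value) && meta$p_value < 0.05
    sens <- if (nrow(recs) >= 2) {
      sensitivity_suite(recs, config$hwe_threshold, config$prefer_counts,
                        config$correction, config$i2_threshold,
                        config$qp_threshold)
    } else NULL
    tables <- allele_tables_from_records(recs)
    harbord <- if (nrow(tables) > 0) {
      harbord_test(tables, min_k = config$harbord_min_k,
                   warn_k = config$harbord_warn_k)
    } else NULL
    fprp <- if (significant) {
      fprp_for_association(meta, config$fprp_priors, config$fprp_target_or,
                           config$fprp_headline_prior)
    } else NULL
    cred <- NULL
    grade_note <- NA_character_
    if (significant) {
      if (is.na(meta$evidence_amount)) {
        grade_note <- "ungraded: no genotype counts to tally the evidence amount"
      } else {
        cred <- grade_association(meta, harbord, sens, fprp,
                                  gwas_replicated = any(recs$gwas_replicated),
                                  harbord_threshold = config$harbord_threshold)
        credibility[[g]] <- cred
      }
    } else {
      grade_note <- "ungraded: association not significant at p < 0.05"
    }
    summary_rows[[g]] <- data.frame(
      variant = recs$variant[1], cancer = recs$cancer[1], k = meta$k,
      or_pooled = meta$or_pooled, ci_low = meta$ci_low,
      ci_high = meta$ci_high, p_value = meta$p_value,
      q_stat = meta$q_stat, q_p = meta$q_p,
      i_squared_pct = meta$i_squared_pct, tau2 = meta$tau2,
      model = meta$model, evidence_amount = meta$evidence_amount,
      significant = significant,
      harbord_p = if (!is.null(harbord) && !harbord$skipped)
        harbord$p_value else NA_real_,
      sensitivity_stable = if (!is.null(sens)) sens$stable else NA,
      fprp_headline = if (!is.null(fprp)) fprp$headline_fprp else NA_real_,
      fprp_category = if (!is.null(fprp)) fprp$category else NA_character_,
      amount_grade = if (!is.null(cred)) cred$amount_grade else NA_character_,
      replication_grade = if (!is.null(cred)) cred$replication_grade else NA_character_,
      bias_grade = if (!is.null(cred)) cred$bias_grade else NA_character_,
      venice_initial = if (!is.null(cred)) cred$venice_initial else NA_character_,
      final_grade = if (!is.null(cred)) cred$final_grade else NA_character_,
      rationale = if (!is.null(cred))
        paste(cred$rationale, collapse = ";") else grade_note,
      stringsAsFactors = FALSE)
    w <- if (meta$model == "random") 1 / (eff$se^2 + meta$tau2) else 1 / eff$se^2
    z975 <- stats::qnorm(0.975)
    forest_rows[[g]] <- data.frame(
      variant = recs$variant[1], cancer = recs$cancer[1],
      study_id = eff$study_id, year = eff$year, or = exp(eff$log_or),
      ci_low = exp(eff$log_or - z975 * eff$se),
      ci_high = exp(eff$log_or + z975 * eff$se),
      weight_pct = 100 * w / sum(w), stringsAsFactors = FALSE)
    if (!is.null(fprp))
      fprp_rows[[g]] <- data.frame(
        variant = recs$variant[1], cancer = recs$cancer[1],
        prior = fprp$priors, power = fprp$power, fprp = fprp$fprp_values,
        stringsAsFactors = FALSE)
  }
  empty_summary <- data.frame(
    variant = character(), cancer = character(), k = integer(),
    or_pooled = numeric(), ci_low = numeric(), ci_high = numeric(),
    p_value = numeric(), q_stat = numeric(), q_p = numeric(),
    i_squared_pct = numeric(), tau2 = numeric(), model = character(),
    evidence_amount = numeric(), significant = logical(),
    harbord_p = numeric(), sensitivity_stable = logical(),
    fprp_headline = numeric(), fprp_category = character(),
    amount_grade = character(), replication_grade = character(),
    bias_grade = character(), venice_initial = character(),
    final_grade = character(), rationale = character(),
    stringsAsFactors = FALSE)
  empty_forest <- data.frame(
    variant = character(), cancer = character(), study_id = character(),
    year = integer(), or = numeric(), ci_low = numeric(),
    ci_high = numeric(), weight_pct = numeric(), stringsAsFactors = FALSE)
  res <- list(summary = if (length(summary_rows) > 0)
                do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
              else empty_summary,
              forest = if (length(forest_rows) > 0)
                do.call(rbind, c(forest_rows, list(make.row.names = FALSE)))
              else empty_forest,
              fprp_table = if (length(fprp_rows) > 0)
                do.call(rbind, c(fprp_rows, list(make.row.names = FALSE)))
              else data.frame(variant = character(), cancer = character(),
                              prior = numeric(), power = numeric(),
                              fprp = numeric(), stringsAsFactors = FALSE),
              credibility = credibility, config = config,
              rejects = catalogue_rejects(records))
  class(res) <- "synopsis"
  res
}

#' @export
print.synopsis <- function(x, ...) {
  cat(sprintf("synopsis: %d associations (%d significant, %d graded)\n",
              nrow(x$summary), sum(x$summary$significant),
              sum(!is.na(x$summary$final_grade))))
  cols <- c("variant", "cancer", "k", "or_pooled", "ci_low", "ci_high",
            "p_value", "i_squared_pct", "model", "final_grade")
  print(x$summary[, cols], digits = 4)
  invisible(x)
}

#' Write synopsis results
#'
#' Emits the per-association results table, the per-study forest table, the
#' FPRP grid, the reject report, and a machine-readable run manifest
#' (configuration, seed, package version, input checksum) to a directory.
#'
#' @param synopsis Output of [run_synopsis()].
#' @param out_dir Output directory (created if absent).
#' @param catalogue_path Optional path of the input catalogue; its MD5 is
#'   recorded in the manifest.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_results <- function(synopsis, out_dir, catalogue_path = NULL) {
  stopifnot(inherits(synopsis, "synopsis"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  if (nrow(synopsis$summary) == 0)
    warning("empty synopsis: writing header-only tables")
  paths <- c(results = file.path(out_dir, "results.tsv"),
             forest = file.path(out_dir, "forest.tsv"),
             fprp = file.path(out_dir, "fprp.tsv"),
             rejects = file.path(out_dir, "rejects.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  wt <- function(df, path)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8", na = "NA")
  wt(synopsis$summary, paths["results"])
  wt(synopsis$forest, paths["forest"])
  wt(synopsis$fprp_table, paths["fprp"])
  wt(synopsis$rejects, paths["rejects"])
  manifest <- list(
    package = "metacred",
    version = as.character(utils::packageVersion("metacred")),
    config = unclass(synopsis$config),
    input = if (!is.null(catalogue_path))
      list(path = catalogue_path,
           md5 = unname(tools::md5sum(catalogue_path))) else NULL,
    n_associations = nrow(synopsis$summary),
    n_significant = sum(synopsis$summary$significant),
    note = "associations graded at nominal p < 0.05; no multiplicity correction")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
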