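# Shared builders for small in-memory catalogues and effects tables.

# One catalogue row from raw fields; counts default to a clean mid-size study.
make_record <- function(study_id = "S1", author = "Author", year = 2005L,
                        cancer = "prostate", variant = "rs0001",
                        ethnicity = "Caucasian", design = "case-control",
                        case_counts = c(120L, 80L, 20L),
                        ctrl_counts = c(140L, 70L, 10L),
                        reported_or = NA_real_, reported_ci_low = NA_real_,
                        reported_ci_high = NA_real_, gwas_replicated = FALSE) {
  data.frame(study_id = study_id, author = author, year = year,
             cancer = cancer, variant = variant, ethnicity = ethnicity,
             design = design,
             case_hom_common = case_counts[1], case_het = case_counts[2],
             case_hom_rare = case_counts[3],
             ctrl_hom_common = ctrl_counts[1], ctrl_het = ctrl_counts[2],
             ctrl_hom_rare = ctrl_counts[3],
             reported_or = reported_or, reported_ci_low = reported_ci_low,
             reported_ci_high = reported_ci_high,
             gwas_replicated = gwas_replicated, stringsAsFactors = FALSE)
}

# k identical studies (useful for degenerate-case checks).
identical_records <- function(k, ...) {
  do.call(rbind, lapply(seq_len(k), function(i)
    make_record(study_id = sprintf("S%02d", i),
                author = sprintf("A%02d", i), year = 2000L + i, ...)))
}

# Effects table straight from log ORs and SEs.
make_effects <- function(log_or, se, year = seq_along(log_or) + 2000L) {
  data.frame(study_id = sprintf("S%02d", seq_along(log_or)), year = year,
             log_or = log_or, se = se, contrast = "allele",
             corrected = FALSE, stringsAsFactors = FALSE)
}

# Write a catalogue data frame to a temp TSV and return the path.
write_temp_catalogue <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  path
}

# Minimal meta-result stand-in for grading tests.
fake_meta <- function(p_value, or_pooled, i_squared_pct = 0,
                      evidence_amount = 5000, k = 5L, pooled_se = 0.05) {
  list(p_value = p_value, or_pooled = or_pooled,
       i_squared_pct = i_squared_pct, evidence_amount = evidence_amount,
       k = k, pooled_se = pooled_se)
}
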