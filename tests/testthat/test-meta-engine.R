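worked_pair <- function() make_effects(c(0, 0.6931), c(0.1, 0.1))

test_that("fixed-effect pooling matches direct arithmetic", {
  one <- pool_fixed(make_effects(0.2, 0.1))
  expect_equal(one$or_pooled, exp(0.2))
  expect_equal(one$ci_low, exp(0.2 - qnorm(0.975) * 0.1))
  expect_equal(one$ci_high, exp(0.2 + qnorm(0.975) * 0.1))
  expect_equal(one$k, 1)
  expect_equal(one$q_stat, 0)

  two <- pool_fixed(worked_pair())
  expect_equal(two$pooled_log_or, 0.34655, tolerance = 1e-4)
  expect_equal(two$pooled_se, 1 / sqrt(200))
  expect_error(pool_fixed(data.frame(log_or = numeric(0), se = numeric(0))),
               "no effect")
})

test_that("heterogeneity statistics match the worked example", {
  het <- heterogeneity(worked_pair())
  expect_equal(het$q_stat, 24.02, tolerance = 1e-3)
  expect_equal(het$i_squared_pct, 95.8, tolerance = 1e-3)
  expect_equal(het$tau2, 0.2302, tolerance = 1e-3)
  expect_equal(het$q_p, pchisq(het$q_stat, 1, lower.tail = FALSE))

  same <- heterogeneity(make_effects(c(0.3, 0.3), c(0.1, 0.1)))
  expect_equal(same$q_stat, 0)
  expect_equal(same$i_squared_pct, 0)
  expect_equal(same$tau2, 0)
  expect_error(heterogeneity(make_effects(0.3, 0.1)), "at least 2")
})

test_that("DerSimonian-Laird pooling matches direct arithmetic", {
  res <- pool_random_dl(worked_pair())
  expect_equal(res$pooled_log_or, 0.34655, tolerance = 1e-4)
  expect_equal(res$pooled_se, 0.3466, tolerance = 1e-3)
  expect_equal(res$model, "random")

  # tau2 = 0 degenerates to the fixed-effect result
  eff <- make_effects(c(0.29, 0.31), c(0.2, 0.2))
  expect_equal(heterogeneity(eff)$tau2, 0)
  fx <- pool_fixed(eff); rd <- pool_random_dl(eff)
  expect_equal(rd$pooled_log_or, fx$pooled_log_or)
  expect_equal(rd$pooled_se, fx$pooled_se)
})

test_that("random-effects CIs are never narrower than fixed-effect CIs", {
  set.seed(11)
  for (i in 1:20) {
    eff <- make_effects(rnorm(6, 0.2, 0.4), runif(6, 0.05, 0.4))
    fx <- pool_fixed(eff); rd <- pool_random_dl(eff)
    expect_gte(rd$ci_high / rd$ci_low, fx$ci_high / fx$ci_low)
  }
})

test_that("pooling is invariant to study order and SE rescaling", {
  set.seed(21)
  eff <- make_effects(rnorm(8, 0.3, 0.3), runif(8, 0.05, 0.5))
  perm <- eff[sample(8), ]
  expect_equal(pool_fixed(perm)$pooled_log_or, pool_fixed(eff)$pooled_log_or)
  expect_equal(heterogeneity(perm), heterogeneity(eff))
  expect_equal(pool_random_dl(perm)$pooled_se, pool_random_dl(eff)$pooled_se)

  scaled <- eff; scaled$se <- eff$se * 3
  expect_equal(pool_fixed(scaled)$pooled_log_or, pool_fixed(eff)$pooled_log_or)

  # pooled estimate always lies within the range of study effects
  for (i in 1:10) {
    e <- make_effects(rnorm(5, 0, 0.5), runif(5, 0.05, 0.5))
    expect_gte(pool_fixed(e)$pooled_log_or, min(e$log_or))
    expect_lte(pool_fixed(e)$pooled_log_or, max(e$log_or))
    expect_gte(pool_random_dl(e)$pooled_log_or, min(e$log_or))
    expect_lte(pool_random_dl(e)$pooled_log_or, max(e$log_or))
  }
})

test_that("pooled results agree with metafor as an independent cross-check", {
  set.seed(31)
  for (i in 1:5) {
    k <- sample(3:8, 1)
    eff <- make_effects(rnorm(k, 0.2, 0.4), runif(k, 0.05, 0.4))
    fe <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "FE")
    fx <- pool_fixed(eff)
    expect_equal(fx$pooled_log_or, as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(fx$pooled_se, fe$se, tolerance = 1e-10)
    expect_equal(fx$q_stat, fe$QE, tolerance = 1e-10)

    dl <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "DL")
    rd <- pool_random_dl(eff)
    expect_equal(rd$pooled_log_or, as.numeric(dl$beta), tolerance = 1e-10)
    expect_equal(rd$pooled_se, dl$se, tolerance = 1e-10)
    expect_equal(rd$tau2, dl$tau2, tolerance = 1e-10)
    expect_equal(rd$i_squared_pct, dl$I2, tolerance = 1e-8)
  }
})

test_that("model selection follows the configured heterogeneity policy", {
  expect_equal(select_model(list(i_squared_pct = 0, q_p = 0.8)), "fixed")
  expect_equal(select_model(list(i_squared_pct = 84.3, q_p = 0.0005)), "random")
  expect_equal(select_model(list(i_squared_pct = 40, q_p = 0.05)), "random")
  expect_equal(select_model(list(i_squared_pct = 40, q_p = 0.2)), "fixed")
  expect_equal(select_model(list(i_squared_pct = 40, q_p = 0.2),
                            i2_threshold = 30), "random")
})

test_that("identical studies give a stable sensitivity suite", {
  recs <- as_study_catalogue(identical_records(5))
  rep <- sensitivity_suite(recs)
  expect_true(rep$stable)
  expect_equal(rep$loo_or_range[1], rep$loo_or_range[2])
  expect_equal(rep$loo_or_range[1], rep$full$or_pooled, tolerance = 1e-12)
  # no HWE violators: the drop-HWE variant is the full result
  expect_equal(rep$drop_hwe_or, rep$full$or_pooled)
})

test_that("an outlier-driven association is flagged unstable", {
  # four tiny exactly-null studies plus one large strongly positive study:
  # the pooled result is significant only because of the outlier
  null_study <- function(id, yr) make_record(id, year = yr,
    case_counts = c(18L, 9L, 3L), ctrl_counts = c(18L, 9L, 3L))
  outlier <- make_record("S9", year = 2015L,
    case_counts = c(800L, 920L, 280L), ctrl_counts = c(980L, 840L, 180L))
  recs <- as_study_catalogue(rbind(
    null_study("S1", 2001L), null_study("S2", 2002L),
    null_study("S3", 2003L), null_study("S4", 2004L), outlier))
  full <- pool_auto(effects_from_records(recs))
  expect_true(full$ci_low > 1)          # significant only due to the outlier
  rep <- sensitivity_suite(recs)
  expect_false(rep$stable)
})

test_that("cumulative meta-analysis accumulates in publication order", {
  recs <- as_study_catalogue(rbind(
    make_record("S1", author = "B", year = 2003L,
                case_counts = c(100L, 90L, 30L)),
    make_record("S2", author = "A", year = 2001L),
    make_record("S3", author = "C", year = 2008L,
                case_counts = c(110L, 85L, 25L))))
  steps <- cumulative_by_year(recs)
  expect_length(steps, 3)
  # first element is the earliest study alone
  first <- pool_fixed(effects_from_records(recs[recs$study_id == "S2", ]))
  expect_equal(steps[[1]]$pooled_log_or, first$pooled_log_or)
  # last element equals the full pooled result
  full <- pool_fixed(effects_from_records(recs))
  expect_equal(steps[[3]]$pooled_log_or, full$pooled_log_or)
  # evidence accumulates monotonically
  amounts <- vapply(steps, function(s) s$evidence_amount, numeric(1))
  expect_true(all(diff(amounts) > 0))

  single <- cumulative_by_year(recs[1, ])
  expect_length(single, 1)
  expect_equal(single[[1]]$k, 1)
})

test_that("subgroup pooling is independent per stratum", {
  recs <- as_study_catalogue(identical_records(4))
  one <- subgroup_meta(recs, "ethnicity")
  expect_length(one, 1)
  expect_equal(one$Caucasian$pooled_log_or,
               pool_auto(effects_from_records(recs))$pooled_log_or)

  recs2 <- identical_records(4)
  recs2$ethnicity <- c("Asian", "Asian", "Caucasian", "Caucasian")
  by_eth <- subgroup_meta(as_study_catalogue(recs2), "ethnicity")
  expect_equal(by_eth$Asian$pooled_log_or, by_eth$Caucasian$pooled_log_or)
})

test_that("subgroup estimates recover stratum-specific effects", {
  cfg_asian <- sim_config(n_studies = 8, or2 = 2.25, lambda = 0.5,
                          n_cases = 2000, n_controls = 2000, seed = 301,
                          ethnicity = "Asian")
  cfg_cauc <- sim_config(n_studies = 8, or2 = 1, lambda = 0.5,
                         n_cases = 2000, n_controls = 2000, seed = 302,
                         ethnicity = "Caucasian")
  recs <- as_study_catalogue(rbind(as.data.frame(simulate_catalogue(cfg_asian)),
                                   as.data.frame(simulate_catalogue(cfg_cauc))))
  recs$study_id <- sprintf("S%02d", seq_len(nrow(recs)))
  by_eth <- subgroup_meta(as_study_catalogue(recs), "ethnicity")
  expect_equal(by_eth$Asian$pooled_log_or, log(1.5), tolerance = 0.12)
  expect_lt(abs(by_eth$Caucasian$pooled_log_or), 0.08)
})

test_that("meta-regression recovers an exact linear trend", {
  x <- c(1, 2, 3, 4, 5)
  eff <- make_effects(0.1 + 0.2 * x, rep(0.1, 5))
  fit <- meta_regression(eff, x)
  expect_equal(fit$slope, 0.2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$slope / fit$slope_se)))
  # permutation invariance
  perm <- sample(5)
  fit2 <- meta_regression(eff[perm, ], x[perm])
  expect_equal(fit2$slope, fit$slope)
  expect_error(meta_regression(eff, rep(1, 5)), "collinearity")
  expect_error(meta_regression(eff[1:2, ], x[1:2]), "at least 3")
})

test_that("meta-regression matches metafor with matched weights", {
  set.seed(41)
  eff <- make_effects(rnorm(8, 0.2, 0.3), runif(8, 0.08, 0.3))
  x <- rnorm(8)
  fit <- meta_regression(eff, x)
  ref <- metafor::rma(yi = eff$log_or, vi = eff$se^2 + fit$tau2,
                      mods = ~x, method = "FE")
  expect_equal(fit$slope, as.numeric(ref$beta[2]), tolerance = 1e-10)
  expect_equal(fit$slope_se, ref$se[2], tolerance = 1e-10)
})

test_that("meta-regression keeps its nominal type-I error under the null", {
  set.seed(51)
  rejections <- 0
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    eff <- make_effects(rnorm(10, 0.2, 0.05), rep(0.05, 10))
    x <- rnorm(10)
    if (meta_regression(eff, x)$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_rep, 0.02)
  expect_lt(rejections / n_rep, 0.10)
})
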