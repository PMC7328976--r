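test_that("amount grade follows the test-allele tally cutpoints", {
  expect_equal(grade_amount(1500), "A")
  expect_equal(grade_amount(1001), "A")
  expect_equal(grade_amount(1000), "B")
  expect_equal(grade_amount(100), "B")
  expect_equal(grade_amount(99), "C")
  expect_equal(grade_amount(0), "C")
  expect_error(grade_amount(-1), "non-negative")
})

test_that("replication grade follows the I-squared cutpoints", {
  expect_equal(grade_replication(10.9), "A")
  expect_equal(grade_replication(24.9), "A")
  expect_equal(grade_replication(25), "B")
  expect_equal(grade_replication(36.2), "B")
  expect_equal(grade_replication(50), "B")
  expect_equal(grade_replication(50.1), "C")
  expect_equal(grade_replication(84.3), "C")
})

test_that("bias grade applies the decision table", {
  # small OR without GWAS replication is C
  expect_equal(grade_bias(1.10), "C")
  expect_equal(grade_bias(0.90), "C")          # symmetric smallness rule
  # GWAS replication rescues a small OR
  expect_equal(grade_bias(1.13, gwas_replicated = TRUE, harbord_p = 0.6,
                          sensitivity_stable = TRUE), "A")
  # clear Harbord + stable + sizeable effect is A
  expect_equal(grade_bias(1.30, harbord_p = 0.6, sensitivity_stable = TRUE), "A")
  # Harbord unavailable: bias could be present
  expect_equal(grade_bias(1.30), "B")
  expect_equal(grade_bias(1.30, harbord_p = NA, sensitivity_stable = TRUE), "B")
  # borderline Harbord (between threshold and twice the threshold) is B
  expect_equal(grade_bias(1.30, harbord_p = 0.15, sensitivity_stable = TRUE), "B")
  # significant Harbord or unstable sensitivity is C
  expect_equal(grade_bias(1.30, harbord_p = 0.05, sensitivity_stable = TRUE), "C")
  expect_equal(grade_bias(1.30, harbord_p = 0.6, sensitivity_stable = FALSE), "C")
  expect_equal(grade_bias(1.30, bias_evident = TRUE), "C")
  expect_error(grade_bias(-1), "positive")
})

test_that("the composite rule maps every grade triple correctly", {
  grades <- c("A", "B", "C")
  for (a in grades) for (r in grades) for (b in grades) {
    expected <- if (all(c(a, r, b) == "A")) "strong"
    else if (any(c(a, r, b) == "C")) "weak"
    else "moderate"
    expect_equal(composite_venice(a, r, b), expected,
                 info = paste(a, r, b))
  }
  expect_equal(composite_venice("A", "A", "A"), "strong")
  expect_equal(composite_venice("A", "B", "A"), "moderate")
  expect_equal(composite_venice("A", "A", "C"), "weak")
  expect_error(composite_venice("A", "D", "A"), "grades")
})

test_that("the FPRP upgrade moves one level when FPRP < 0.05", {
  expect_equal(apply_fprp_upgrade("moderate", "<0.05"), "strong")
  expect_equal(apply_fprp_upgrade("weak", "<0.05"), "moderate")
  expect_equal(apply_fprp_upgrade("strong", "<0.05"), "strong")
  expect_equal(apply_fprp_upgrade("weak", "0.05-0.20"), "weak")
  expect_equal(apply_fprp_upgrade("moderate", "0.05-0.20"), "moderate")
  expect_equal(apply_fprp_upgrade("strong", ">0.20"), "strong")
  expect_error(apply_fprp_upgrade("weakish", "<0.05"), "grade")
  expect_error(apply_fprp_upgrade("weak", "0.3"), "category")
})

test_that("grade functions are order-respecting", {
  ord <- function(g) match(g, c("weak", "moderate", "strong"))
  # worsening any dimension never improves the composite
  grades <- c("A", "B", "C")
  for (a in 1:3) for (r in 1:3) for (b in 1:3) {
    base <- composite_venice(grades[a], grades[r], grades[b])
    for (dim in 1:3) {
      idx <- c(a, r, b)
      if (idx[dim] < 3) {
        idx[dim] <- idx[dim] + 1
        worse <- composite_venice(grades[idx[1]], grades[idx[2]], grades[idx[3]])
        expect_lte(ord(worse), ord(base))
      }
    }
  }
  # and a worse FPRP category never improves the final grade
  for (g in c("weak", "moderate", "strong")) {
    finals <- vapply(fprp_categories(), function(fc)
      apply_fprp_upgrade(g, fc), character(1))
    expect_true(all(diff(ord(finals)) <= 0))
  }
})

test_that("grade_association chains the rules and records its rationale", {
  meta <- fake_meta(p_value = 1e-6, or_pooled = 1.4, i_squared_pct = 10,
                    evidence_amount = 5000)
  harbord <- list(skipped = FALSE, p_value = 0.7)
  sens <- list(stable = TRUE)
  rec <- grade_association(meta, harbord, sens, fprp = "<0.05")
  expect_equal(rec$amount_grade, "A")
  expect_equal(rec$replication_grade, "A")
  expect_equal(rec$bias_grade, "A")
  expect_equal(rec$venice_initial, "strong")
  expect_equal(rec$final_grade, "strong")
  expect_true(any(grepl("VENICE_STRONG", rec$rationale)))
})

test_that("grading refuses non-significant associations", {
  meta <- fake_meta(p_value = 0.2, or_pooled = 1.3)
  expect_error(grade_association(meta, fprp = "<0.05"), "non-significant")
})

test_that("a C amount grade still admits the FPRP upgrade", {
  # tiny evidence base (k = 2, 80 test alleles) with FPRP < 0.05:
  # composite weak, upgraded to moderate
  meta <- fake_meta(p_value = 0.01, or_pooled = 2.0, i_squared_pct = 5,
                    evidence_amount = 80, k = 2L)
  rec <- grade_association(meta, harbord = NULL, sens = list(stable = TRUE),
                           fprp = "<0.05")
  expect_equal(rec$amount_grade, "C")
  expect_equal(rec$venice_initial, "weak")
  expect_equal(rec$final_grade, "moderate")
})

test_that("single-study associations get replication grade C", {
  meta <- fake_meta(p_value = 0.001, or_pooled = 1.8, i_squared_pct = 0,
                    evidence_amount = 4000, k = 1L)
  rec <- grade_association(meta, fprp = ">0.20")
  expect_equal(rec$replication_grade, "C")
  expect_equal(rec$venice_initial, "weak")
})

test_that("summary-mode grading reproduces the published partition", {
  fx <- load_8q24_synopsis()
  graded <- grade_summaries(fx)
  expect_equal(nrow(graded), 23)
  expect_equal(graded$venice_initial, fx$venice_initial[fx$significant])
  expect_equal(graded$final_grade, fx$final_grade[fx$significant])
  counts <- table(graded$final_grade)
  expect_equal(as.integer(counts[c("strong", "moderate", "weak")]),
               c(6L, 13L, 4L))
  # the published upgrade examples
  pick <- function(v, c) graded[graded$variant == v & graded$cancer == c, ]
  expect_equal(pick("rs7000448", "prostate")$venice_initial, "moderate")
  expect_equal(pick("rs7000448", "prostate")$final_grade, "strong")
  expect_equal(pick("rs16901979", "prostate")$final_grade, "moderate")
  expect_equal(pick("rs9642880", "bladder")$final_grade, "strong")
  expect_equal(pick("rs1447295", "stomach")$final_grade, "moderate")
  expect_equal(pick("rs13254738", "prostate")$final_grade, "weak")
})
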