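test_that("score categorization respects the 35/66 cutoffs and their boundaries", {
  expect_identical(categorize_score(c(34.9, 35, 65.9, 66, 0, 100)),
                   c("negative", "uncertain", "uncertain", "positive",
                     "negative", "positive"))
  # lowered automatic-acceptance cutoff for the sensitivity analysis
  thr60 <- triage_thresholds(positive_at_or_above = 60)
  expect_identical(categorize_score(63, thr60), "positive")
  expect_error(categorize_score(101), "\\[0, 100\\]")
  expect_error(categorize_score(-0.1), "\\[0, 100\\]")
})

test_that("threshold objects validate their ordering", {
  expect_error(triage_thresholds(negative_below = 70), "negative_below")
  expect_error(triage_thresholds(final_positive_at_or_above = 0), "final")
})

test_that("the final score is the stated three-way mean on a common 0-100 scale", {
  expect_equal(final_score(35, 1, 1), (35 + 200) / 3)
  expect_equal(round(final_score(35, 1, 1), 2), 78.33)
  expect_equal(round(final_score(65.9, 0, 0), 2), 21.97)
  expect_equal(final_score(50, 1, 0), 50)
  expect_error(final_score(50, NA, 1), "escalation incomplete")
  expect_error(final_score(50, 1, 2), "r2")
})

test_that("unanimous reviewers decide every uncertain case; split reviewers defer to the AI score at 50", {
  grid <- seq(35, 65.9, by = 0.1)
  thr <- triage_thresholds()
  expect_true(all(final_score(grid, 1, 1) >= 50))   # min (35+200)/3 = 78.3
  expect_true(all(final_score(grid, 0, 0) < 50))    # max 65.9/3 = 22.0
  split_verdict <- final_score(grid, 1, 0) >= thr$final_positive_at_or_above
  expect_identical(split_verdict, grid >= 50)
  split_verdict2 <- final_score(grid, 0, 1) >= thr$final_positive_at_or_above
  expect_identical(split_verdict2, grid >= 50)
})

test_that("the final verdict is monotone in the AI score and in each reviewer verdict", {
  grid <- seq(35, 65.9, by = 0.3)
  for (r1 in 0:1) for (r2 in 0:1) {
    v <- as.integer(final_score(grid, r1, r2) >= 50)
    expect_true(all(diff(v) >= 0))
  }
  for (s in c(35, 49.9, 50, 65.9)) {
    expect_true(final_score(s, 0, 0) <= final_score(s, 1, 0))
    expect_true(final_score(s, 1, 0) <= final_score(s, 1, 1))
  }
})

test_that("computing on a 0-1 scale yields identical verdicts", {
  set.seed(8)
  score <- runif(200, 35, 65.99)
  r1 <- rbinom(200, 1, 0.5); r2 <- rbinom(200, 1, 0.5)
  v100 <- final_score(score, r1, r2) >= 50
  v1 <- (score / 100 + r1 + r2) / 3 >= 0.5
  expect_identical(v100, v1)
})

test_that("run_index_test short-circuits auto cases and escalates uncertain ones", {
  cohort <- data.frame(
    case_id = c("a", "b", "c"),
    true_status = NA_integer_, ai_score = c(70, 40, 49.9),
    ct_compatible = 1L, dlco_available = 1L,
    ref_verdict_1 = 1L, ref_verdict_2 = 1L, ref_verdict_3 = 1L,
    index_verdict_1 = c(NA, 1L, 1L), index_verdict_2 = c(NA, 1L, 0L)
  )
  out <- run_index_test(cohort)
  expect_identical(out$category, c("positive", "uncertain", "uncertain"))
  expect_identical(out$index_verdict, c(1L, 1L, 0L))
  expect_true(is.na(out$final_score[1]))
  expect_equal(out$final_score[2], 80)
  expect_equal(out$final_score[3], (49.9 + 100) / 3)
})

test_that("incomplete escalations and missing scores raise named errors; a fallback hook fills missing scores", {
  cohort <- data.frame(
    case_id = c("u1", "u2"), true_status = NA_integer_,
    ai_score = c(40, NA), ct_compatible = c(1L, 0L), dlco_available = 1L,
    ref_verdict_1 = 0L, ref_verdict_2 = 0L, ref_verdict_3 = 0L,
    index_verdict_1 = c(NA_integer_, NA_integer_),
    index_verdict_2 = c(NA_integer_, NA_integer_)
  )
  expect_error(run_index_test(cohort[2, ]), "u2.*no fallback")
  expect_error(run_index_test(cohort[1, ]), "escalation incomplete.*u1")
  out <- run_index_test(cohort[2, ], fallback = function(case) 80)
  expect_identical(out$index_verdict, 1L)
})

test_that("triage_summary counts match a brute-force recount and sum to the cohort size", {
  cohort <- generate_cohort(sim_config(n_cases = 300, seed = 14))
  out <- run_index_test(cohort)
  s <- triage_summary(out)
  recount <- table(factor(categorize_score(cohort$ai_score),
                          levels = c("negative", "uncertain", "positive")))
  expect_identical(as.integer(s$categories), as.integer(recount))
  expect_identical(sum(s$categories), s$n)
  expect_identical(s$approved_total + s$denied_total, s$n)

  empty <- triage_summary(out[0, ])
  expect_identical(sum(empty$categories), 0L)
})
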