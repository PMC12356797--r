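test_that("confusion counts match a brute-force pair loop and round-trip a fixture", {
  fx <- make_confusion_fixture()
  cc <- confusion(fx$pred, fx$ref)
  expect_identical(unclass(cc)[c("tp", "fp", "tn", "fn")],
                   list(tp = 49L, fp = 5L, tn = 30L, fn = 8L))

  set.seed(17)
  for (rep in 1:5) {
    pred <- rbinom(40, 1, 0.5); ref <- rbinom(40, 1, 0.5)
    cc <- confusion(pred, ref)
    brute <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    for (i in seq_along(pred)) {
      key <- if (pred[i] == 1 && ref[i] == 1) "tp"
             else if (pred[i] == 1) "fp"
             else if (ref[i] == 0) "tn" else "fn"
      brute[key] <- brute[key] + 1L
    }
    expect_identical(c(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn), brute)
  }
  expect_identical(confusion(c(0, 1), c(0, 1))$fp, 0L)
  expect_error(confusion(1, c(1, 0)), "length")
})

test_that("point metrics follow their defining ratios and flag undefined denominators", {
  cc <- confusion(make_confusion_fixture()$pred, make_confusion_fixture()$ref)
  pm <- point_metrics(cc)
  expect_equal(round(pm[["sensitivity"]], 2), 0.86)  # 49/57
  expect_equal(pm[["specificity"]], 30 / 35)
  expect_equal(pm[["accuracy"]], 79 / 92)

  set.seed(23)
  for (rep in 1:10) {
    k <- as.list(rmultinom(1, 80, rep(1 / 4, 4))[, 1])
    names(k) <- c("tp", "fp", "tn", "fn")
    pm <- point_metrics(k)
    expect_equal(pm[["ppv"]], with(k, tp / (tp + fp)))
    expect_equal(pm[["npv"]], with(k, tn / (tn + fn)))
  }
  eq <- point_metrics(list(tp = 5, fp = 5, tn = 5, fn = 5))
  expect_true(all(eq == 0.5))
  all_pred_pos <- point_metrics(list(tp = 5, fp = 5, tn = 0, fn = 0))
  expect_true(is.na(all_pred_pos[["npv"]]))      # tn + fn = 0
  all_ref_pos <- point_metrics(list(tp = 5, fp = 0, tn = 0, fn = 5))
  expect_true(is.na(all_ref_pos[["specificity"]])) # tn + fp = 0
})

test_that("ROC-AUC equals the pairwise Mann-Whitney oracle and its closed-form extremes", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(4, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(6:25, 1)
    scores <- sample(1:8, n, replace = TRUE)  # force ties
    ref <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, ref), oracle_auc_pairs(scores, ref))
  }
  expect_warning(expect_true(is.na(roc_auc(1:4, rep(1, 4)))), "one class")
})

test_that("ROC-AUC is invariant under strictly monotone score transforms", {
  set.seed(43)
  scores <- runif(60, 0, 100)
  ref <- rbinom(60, 1, 0.5)
  base <- roc_auc(scores, ref)
  expect_equal(roc_auc(log(scores + 1), ref), base)
  expect_equal(roc_auc(scores^3, ref), base)
  expect_equal(roc_auc(rank(scores), ref), base)
})

test_that("ROC-AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  scores <- c(runif(30, 20, 80), runif(30, 40, 100))
  ref <- rep(c(0, 1), each = 30)
  expect_equal(roc_auc(scores, ref),
               as.numeric(pROC::auc(pROC::roc(ref, scores, quiet = TRUE))))
})

test_that("PR-AUC equals exhaustive threshold enumeration and the uninformative baseline", {
  expect_equal(pr_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(6:25, 1)
    scores <- sample(1:6, n, replace = TRUE)
    ref <- c(1, rbinom(n - 1, 1, 0.5))
    expect_equal(pr_auc(scores, ref), oracle_average_precision(scores, ref))
  }
  # random scores: average precision converges to prevalence
  set.seed(59)
  scores <- runif(20000)
  ref <- rbinom(20000, 1, 0.3)
  expect_equal(pr_auc(scores, ref), 0.3, tolerance = 0.02)
  expect_warning(expect_true(is.na(pr_auc(1:4, rep(0, 4)))), "no positive")
})

test_that("accuracy decomposes as prevalence-weighted sensitivity and specificity", {
  set.seed(61)
  for (rep in 1:10) {
    pred <- rbinom(50, 1, 0.5)
    ref <- c(0, 1, rbinom(48, 1, 0.5))
    pm <- point_metrics(confusion(pred, ref))
    prev <- mean(ref)
    expect_equal(pm[["accuracy"]],
                 prev * pm[["sensitivity"]] + (1 - prev) * pm[["specificity"]])
  }
})

test_that("the bootstrap is deterministic under a fixed seed, bounded, and zero-width for constants", {
  fx <- make_confusion_fixture()
  sens <- function(d) sum(d$pred == 1 & d$ref == 1) / max(1, sum(d$ref == 1))
  a <- bootstrap_ci(sens, fx, n_boot = 2000, seed = 5)
  b <- bootstrap_ci(sens, fx, n_boot = 2000, seed = 5)
  expect_identical(a[c("point", "ci_low", "ci_high", "n_skipped")],
                   b[c("point", "ci_low", "ci_high", "n_skipped")])
  expect_true(a$ci_low <= a$point && a$point <= a$ci_high)
  expect_true(a$ci_low >= 0 && a$ci_high <= 1)

  const <- bootstrap_ci(function(d) 0.7, fx, n_boot = 100, seed = 1)
  expect_identical(c(const$ci_low, const$ci_high), c(0.7, 0.7))
})

test_that("degenerate resamples are skipped and counted, and an all-degenerate bootstrap errors", {
  data <- list(ref = c(1, rep(0, 11)), pred = rep(1, 12))
  sens <- function(d) if (!any(d$ref == 1)) NA_real_ else
    sum(d$pred == 1 & d$ref == 1) / sum(d$ref == 1)
  est <- bootstrap_ci(sens, data, n_boot = 500, seed = 3)
  expect_gt(est$n_skipped, 0)
  expect_lt(est$n_skipped, 500)
  expect_error(bootstrap_ci(function(d) NA_real_, data, n_boot = 50, seed = 1),
               "degenerate")
})

test_that("paired AUC comparison: identical scores give zero difference and p = 1, and the DeLong AUC matches roc_auc", {
  set.seed(67)
  scores <- runif(80)
  ref <- c(0, 1, rbinom(78, 1, 0.5))
  same <- compare_auc_paired(scores, scores, ref)
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)
  other <- runif(80)
  cmp <- compare_auc_paired(scores, other, ref)
  expect_equal(cmp$auc_a, roc_auc(scores, ref))
  expect_equal(cmp$auc_b, roc_auc(other, ref))
})

test_that("the DeLong test agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  ref <- rep(c(0, 1), each = 40)
  a <- rnorm(80) + 0.8 * ref
  b <- rnorm(80) + 0.5 * ref
  ours <- compare_auc_paired(a, b, ref)
  theirs <- pROC::roc.test(pROC::roc(ref, a, quiet = TRUE),
                           pROC::roc(ref, b, quiet = TRUE),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p_value, as.numeric(theirs$p.value), tolerance = 1e-8)
})

test_that("the DeLong test keeps its nominal type-I error under the null", {
  set.seed(73)
  rejections <- 0
  n_sim <- 300
  for (i in seq_len(n_sim)) {
    ref <- rep(c(0, 1), each = 50)
    a <- rnorm(100); b <- rnorm(100)  # both uninformative: AUCs equal in law
    if (compare_auc_paired(a, b, ref)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_sim, 0.02)
  expect_lt(rejections / n_sim, 0.09)
})

test_that("the paired bootstrap comparison is available and directionally consistent with DeLong", {
  set.seed(79)
  ref <- rep(c(0, 1), each = 30)
  a <- rnorm(60) + 1.2 * ref
  b <- rnorm(60)
  dl <- compare_auc_paired(a, b, ref)
  bs <- compare_auc_paired(a, b, ref, method = "bootstrap", n_boot = 1000,
                           seed = 2)
  expect_equal(bs$diff, dl$diff)
  expect_lt(bs$p_value, 0.1)
})
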