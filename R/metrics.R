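#' Cross-tabulate index verdicts against the reference standard
#'
#' @param pred Binary vector of index-test verdicts.
#' @param ref Binary vector of reference-standard labels, same length.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`, `n`.
#' @export
confusion <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stopf("`pred` (%d) and `ref` (%d) differ in length",
          length(pred), length(ref))
  }
  if (length(pred) < 1L) stopf("need at least one case")
  if (any(is.na(pred)) || any(is.na(ref))) stopf("missing verdicts in input")
  check_binary(pred, "pred")
  check_binary(ref, "ref")
  structure(list(
    tp = sum(pred == 1 & ref == 1),
    fp = sum(pred == 1 & ref == 0),
    tn = sum(pred == 0 & ref == 0),
    fn = sum(pred == 0 & ref == 1),
    n = length(pred)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (n = %d): TP %d, FP %d, TN %d, FN %d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Point diagnostic accuracy metrics from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`. A metric whose
#' denominator is zero is undefined and returned as `NA` (never silently 0).
#'
#' @param cc A [confusion()] object, or a list with fields tp/fp/tn/fn.
#' @return Named numeric vector: sensitivity, specificity, accuracy, ppv, npv.
#' @export
point_metrics <- function(cc) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  with(cc, c(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = ratio(tp + tn, tp + fp + tn + fn),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  ))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Rank-based ROC-AUC: the probability that a randomly chosen positive case
#' scores higher than a randomly chosen negative one, with half credit for
#' ties. Invariant under strictly monotone transformations of the scores.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param ref Binary reference labels.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if only one class is
#'   present.
#' @export
roc_auc <- function(scores, ref) {
  stopifnot(length(scores) == length(ref))
  if (any(is.na(scores)) || any(is.na(ref))) stopf("missing values in input")
  check_binary(ref, "ref")
  n_pos <- sum(ref == 1)
  n_neg <- sum(ref == 0)
  if (n_pos == 0L || n_neg == 0L) {
    warning("ROC-AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[ref == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision estimator: scores are swept in decreasing order and the
#' precision at each distinct threshold is weighted by the recall increment
#' it produces (step interpolation, not trapezoidal, which would be
#' optimistic between PR points). For an uninformative ranker this converges
#' to the prevalence of positives.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`, or `NA` (with a warning) if there are no
#'   positives.
#' @export
pr_auc <- function(scores, ref) {
  stopifnot(length(scores) == length(ref))
  if (any(is.na(scores)) || any(is.na(ref))) stopf("missing values in input")
  check_binary(ref, "ref")
  n_pos <- sum(ref == 1)
  if (n_pos == 0L) {
    warning("PR-AUC undefined: no positive cases", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- ref[ord]
  # group ties: cumulate counts at each distinct threshold
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  cum_tp <- cumsum(y)[last_of_group]
  cum_n <- last_of_group
  recall <- cum_tp / n_pos
  precision <- cum_tp / cum_n
  sum(precision * diff(c(0, recall)))
}

#' Percentile bootstrap confidence interval for a cohort statistic
#'
#' Resamples cases (rows) with replacement, recomputes the statistic on each
#' resample, and reports the percentile interval. Resamples on which the
#' statistic is undefined (returns `NA`, e.g. a class absent from the
#' resample) are skipped and counted, not silently dropped. Deterministic
#' under `seed`.
#'
#' @param statistic Function of the (resampled) data returning one number,
#'   or `NA` when undefined on that resample.
#' @param data A data.frame, matrix, or list of equal-length vectors; rows /
#'   elements are resampled jointly.
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param name Label for the estimate.
#' @return Object of class `metric_estimate`: `name`, `point` (statistic on
#'   the original data), `ci_low`, `ci_high`, `n_boot`, `n_skipped`, `seed`,
#'   `conf`.
#' @export
bootstrap_ci <- function(statistic, data, n_boot = 10000, seed = 1L,
                         conf = 0.95, name = "statistic") {
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  check_probability(conf, "conf", allow_zero = FALSE, allow_one = FALSE)
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else length(data[[1]])
  if (is.null(n) || n < 1L) stopf("`data` must contain at least one case")
  take <- if (is.data.frame(data) || is.matrix(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) lapply(data, `[`, idx)
  }
  point <- statistic(data)
  set.seed(check_count(seed, "seed"))
  vals <- vapply(seq_len(n_boot), function(b) {
    as.numeric(statistic(take(sample.int(n, n, replace = TRUE))))
  }, numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) stopf("all %d bootstrap resamples were degenerate", n_boot)
  alpha <- 1 - conf
  qs <- stats::quantile(vals[ok], c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(name = name, point = point,
                 ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, n_skipped = sum(!ok),
                 seed = seed, conf = conf),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3f (%.0f%% CI: %.3f-%.3f; %d bootstrap iterations, %d degenerate resamples skipped, seed %d)\n",
              x$name, x$point, 100 * x$conf, x$ci_low, x$ci_high,
              x$n_boot, x$n_skipped, x$seed))
  invisible(x)
}

# DeLong placement values: for each positive case, the fraction of negatives
# it outranks (ties half), and symmetrically for negatives.
delong_placements <- function(scores, ref) {
  pos <- scores[ref == 1]
  neg <- scores[ref == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Paired comparison of two correlated ROC-AUCs
#'
#' Tests whether two score sets evaluated on the same cases have equal
#' ROC-AUC, accounting for the correlation induced by the shared cases.
#' The default is DeLong's nonparametric method (placement-value covariance
#' and a two-sided normal test); a paired case-resampling bootstrap is
#' offered as an alternative.
#'
#' @param scores_a,scores_b Numeric score vectors on the same cases.
#' @param ref Binary reference labels.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap settings (used when `method = "bootstrap"`).
#' @return A list of class `auc_comparison`: `auc_a`, `auc_b`, `diff`,
#'   `se` (DeLong only), `p_value`, `method`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, ref,
                               method = c("delong", "bootstrap"),
                               n_boot = 10000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(scores_a) == length(ref), length(scores_b) == length(ref))
  check_binary(ref, "ref")
  if (sum(ref == 1) == 0L || sum(ref == 0) == 0L) {
    stopf("paired AUC comparison needs both classes present")
  }
  pa <- delong_placements(scores_a, ref)
  pb <- delong_placements(scores_b, ref)
  d <- pa$auc - pb$auc
  if (method == "delong") {
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
    if (var_d <= .Machine$double.eps) {
      p <- if (abs(d) < .Machine$double.eps^0.5) 1 else 0
      se <- sqrt(max(var_d, 0))
    } else {
      se <- sqrt(var_d)
      p <- 2 * stats::pnorm(-abs(d) / se)
    }
    out <- list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = se,
                p_value = p, method = "delong")
  } else {
    set.seed(check_count(seed, "seed"))
    n <- length(ref)
    diffs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- ref[idx]
      if (sum(r == 1) == 0L || sum(r == 0) == 0L) return(NA_real_)
      roc_auc(scores_a[idx], r) - roc_auc(scores_b[idx], r)
    }, numeric(1))
    diffs <- diffs[!is.na(diffs)]
    # two-sided p: how far the null value 0 sits in the bootstrap distribution
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    p <- min(1, max(p, 1 / length(diffs)))
    out <- list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = stats::sd(diffs),
                p_value = p, method = "bootstrap")
  }
  structure(out, class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("Paired ROC-AUC comparison (%s): AUC_a %.3f vs AUC_b %.3f, diff %.3f, p = %.4f\n",
              x$method, x$auc_a, x$auc_b, x$diff, x$p_value))
  invisible(x)
}
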