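#' Exact binomial upper-tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, computed by summing the upper-tail
#' probability masses from the smallest term upward (numerically stable
#' ordering). This is the exact power of a success criterion requiring at
#' least `k` correct classifications out of `n` when the true per-case
#' probability is `p`.
#'
#' @param n Number of trials.
#' @param k Success threshold, `0 <= k <= n`.
#' @param p Per-trial success probability.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' exact_power(59, 55, 0.98) # 0.9935, the power of the 55-of-59 criterion
exact_power <- function(n, k, p) {
  n <- check_count(n, "n", min = 1L)
  k <- check_count(k, "k", min = 0L)
  if (k > n) stopf("`k` (%d) cannot exceed `n` (%d)", k, n)
  check_probability(p, "p")
  if (k == 0L) return(1)
  terms <- stats::dbinom(k:n, n, p)
  sum(sort(terms))
}

#' Largest success threshold achieving a target power
#'
#' Finds the largest `k` such that `P(X >= k) >= power_target` for
#' `X ~ Binomial(n, p)` — the strictest success criterion that a procedure
#' with true per-case probability `p` would still meet with the required
#' power. Always exists since `P(X >= 0) = 1`.
#'
#' @param n Number of trials.
#' @param p Per-trial success probability.
#' @param power_target Required probability of meeting the criterion,
#'   in `(0, 1)`.
#' @return Integer threshold `k` in `0..n`.
#' @export
#' @examples
#' max_threshold(59, 0.98, 0.99) # 55
max_threshold <- function(n, p, power_target) {
  n <- check_count(n, "n", min = 1L)
  check_probability(p, "p")
  check_probability(power_target, "power_target", allow_zero = FALSE,
                    allow_one = FALSE)
  for (k in n:0) {
    if (exact_power(n, k, p) >= power_target) return(k)
  }
  0L # unreachable: k = 0 always has power 1
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile interval for a binomial proportion `k/n`. The two-sided
#' interval uses `alpha/2` in each tail; the one-sided variant returns
#' `[lower, 1]` with the full `alpha` in the lower tail, matching a one-sided
#' non-inferiority test on a sensitivity.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param alpha Significance level (default 0.05).
#' @param sidedness `"two_sided"` (default) or `"one_sided"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05,
                            sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  n <- check_count(n, "n", min = 1L)
  k <- check_count(k, "k", min = 0L)
  if (k > n) stopf("`k` (%d) cannot exceed `n` (%d)", k, n)
  check_probability(alpha, "alpha", allow_zero = FALSE, allow_one = FALSE)
  a_low <- if (sidedness == "two_sided") alpha / 2 else alpha
  lower <- if (k == 0L) 0 else stats::qbeta(a_low, k, n - k + 1)
  upper <- if (sidedness == "one_sided") 1
           else if (k == n) 1
           else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Exact binomial design for one-sided sensitivity validation
#'
#' Finds the smallest number of reference-positive cases `n` such that the
#' strictest success criterion `k = max_threshold(n, p_true, power_target)`
#' has a Clopper-Pearson lower confidence bound for `k/n` at or above
#' `lower_bound`. The returned design is the study's inclusion-stop rule:
#' recruit until `n` reference positives, declare success iff at least `k`
#' are correctly classified.
#'
#' With the anticipated sensitivity 0.98, power 0.99 and lower bound 0.85,
#' the one-sided 95% convention yields the 55-of-59 criterion (point
#' sensitivity 93%).
#'
#' @param p_true Anticipated sensitivity (default 0.98).
#' @param lower_bound Required lower confidence bound for the criterion
#'   sensitivity `k/n` (default 0.85).
#' @param power_target Required power (default 0.99).
#' @param ci_method `"two_sided"` (default) or `"one_sided"`
#'   Clopper-Pearson convention for the lower bound.
#' @param alpha Confidence level complement (default 0.05).
#' @param n_max Search cap for `n` (default 10000); the scan is linear, exact
#'   over fast.
#' @return Object of class `power_design`: `n_positives`, `k_threshold`,
#'   `point_sensitivity` (`k/n`), `power_achieved`, `ci` (Clopper-Pearson for
#'   `k/n`), plus the design inputs.
#' @export
#' @examples
#' design_study(ci_method = "one_sided") # 55 of 59
design_study <- function(p_true = 0.98, lower_bound = 0.85,
                         power_target = 0.99,
                         ci_method = c("two_sided", "one_sided"),
                         alpha = 0.05, n_max = 10000) {
  ci_method <- match.arg(ci_method)
  check_probability(p_true, "p_true", allow_zero = FALSE, allow_one = FALSE)
  check_probability(lower_bound, "lower_bound", allow_zero = FALSE,
                    allow_one = FALSE)
  check_probability(power_target, "power_target", allow_zero = FALSE,
                    allow_one = FALSE)
  if (lower_bound >= p_true) {
    stopf("design unreachable: lower_bound (%g) must be below the anticipated sensitivity (%g)",
          lower_bound, p_true)
  }
  for (n in seq_len(n_max)) {
    k <- max_threshold(n, p_true, power_target)
    if (k == 0L) next
    ci <- clopper_pearson(k, n, alpha = alpha, sidedness = ci_method)
    if (ci[["lower"]] >= lower_bound) {
      return(structure(list(
        n_positives = n, k_threshold = k,
        point_sensitivity = k / n,
        power_achieved = exact_power(n, k, p_true),
        ci = ci,
        p_true = p_true, lower_bound = lower_bound,
        power_target = power_target, ci_method = ci_method, alpha = alpha
      ), class = "power_design"))
    }
  }
  stopf("design unreachable within n_max = %d: no n gives a %s Clopper-Pearson lower bound >= %g at power %g",
        n_max, ci_method, lower_bound, power_target)
}

#' @export
print.power_design <- function(x, ...) {
  cat("Exact binomial sensitivity-validation design\n")
  cat(sprintf("  anticipated sensitivity %.3f, power target %.2f, lower bound %.2f (%s Clopper-Pearson, alpha %.2f)\n",
              x$p_true, x$power_target, x$lower_bound,
              gsub("_", "-", x$ci_method), x$alpha))
  cat(sprintf("  success criterion: %d of %d reference positives correctly classified\n",
              x$k_threshold, x$n_positives))
  cat(sprintf("  point sensitivity at criterion: %.1f%%; achieved power %.4f; CI for k/n: %.3f-%.3f\n",
              100 * x$point_sensitivity, x$power_achieved,
              x$ci[["lower"]], x$ci[["upper"]]))
  invisible(x)
}
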