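#' Ratings matrix for multi-rater agreement
#'
#' Validates and normalises an items-by-raters matrix of categorical ratings.
#' Items with any missing rating are excluded listwise and counted (the
#' attribute `n_excluded`), mirroring the handling of a panel with a missing
#' verdict; no imputation is performed.
#'
#' @param x Matrix or data.frame, rows = items, columns = raters.
#' @return An integer/character matrix of complete items with attribute
#'   `n_excluded`.
#' @export
ratings_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stopf("ratings must be an items x raters matrix")
  if (ncol(x) < 2L) stopf("agreement needs at least 2 raters")
  complete <- rowSums(is.na(x)) == 0
  out <- x[complete, , drop = FALSE]
  if (nrow(out) < 1L) stopf("no complete items in ratings matrix")
  attr(out, "n_excluded") <- sum(!complete)
  out
}

# Mean per-item pairwise agreement: for item i with counts n_ik per category,
# agreeing pairs = sum_k choose(n_ik, 2) out of choose(m, 2).
pairwise_agreement <- function(R) {
  m <- ncol(R)
  per_item <- apply(R, 1, function(row) {
    counts <- table(row)
    sum(choose(counts, 2)) / choose(m, 2)
  })
  mean(per_item)
}

#' Free-marginal (Randolph) multi-rater kappa
#'
#' Chance-corrected agreement with the chance term fixed at `1/c` for `c`
#' categories, independent of the observed verdict marginals — for binary
#' verdicts the chance of agreeing on a diagnosis is fixed at 0.5. Defined as
#' `(Po - 1/c) / (1 - 1/c)` where `Po` is the mean per-item proportion of
#' agreeing rater pairs. For two raters and two categories this reduces to
#' `2 * Po - 1`.
#'
#' @param R Ratings matrix (items x raters); passed through
#'   [ratings_matrix()].
#' @param n_categories Number of rating categories `c`; defaults to the
#'   number of distinct observed ratings, with a minimum of 2.
#' @return Kappa, in `[-1/(c-1) * (1/(1-1/c)), 1]` (1 = perfect agreement,
#'   0 = chance level).
#' @export
#' @examples
#' randolph_kappa(rbind(c(1, 1, 1), c(1, 1, 0))) # 1/3
randolph_kappa <- function(R, n_categories = NULL) {
  R <- ratings_matrix(R)
  c_ <- if (is.null(n_categories)) max(2L, length(unique(as.vector(R)))) else
    check_count(n_categories, "n_categories", min = 2L)
  po <- pairwise_agreement(R)
  pe <- 1 / c_
  (po - pe) / (1 - pe)
}

#' Fleiss multi-rater kappa
#'
#' Chance-corrected agreement with the chance term computed from the
#' empirical category marginals (`Pe = sum_k p_k^2`), in contrast to the
#' free-marginal kappa which fixes it at `1/c`. When every rating falls in a
#' single category the chance agreement is 1 and kappa is undefined (`NA`
#' with a warning).
#'
#' @inheritParams randolph_kappa
#' @return Kappa, or `NA` when the marginals are degenerate.
#' @export
fleiss_kappa <- function(R) {
  R <- ratings_matrix(R)
  m <- ncol(R)
  cats <- sort(unique(as.vector(R)))
  counts <- vapply(cats, function(k) rowSums(R == k), numeric(nrow(R)))
  counts <- matrix(counts, nrow = nrow(R))
  p_k <- colSums(counts) / (nrow(R) * m)
  pe <- sum(p_k^2)
  if (1 - pe < .Machine$double.eps) {
    warning("Fleiss kappa undefined: all ratings in one category", call. = FALSE)
    return(NA_real_)
  }
  po <- pairwise_agreement(R)
  (po - pe) / (1 - pe)
}

#' Agreement per triage stratum
#'
#' Computes the free-marginal kappa within each stratum of a grouping
#' variable (typically the triage category of the AI score) and overall.
#' Strata with fewer than one complete item are reported as absent (`NA`),
#' never as 0.
#'
#' @param R Ratings matrix (items x raters).
#' @param groups Vector of stratum labels, one per item (row of `R`).
#' @return A data.frame with columns `group`, `n_items`, `kappa`; the last
#'   row (`"overall"`) pools all items.
#' @export
subgroup_kappas <- function(R, groups) {
  if (is.data.frame(R)) R <- as.matrix(R)
  stopifnot(nrow(R) == length(groups))
  lev <- unique(groups)
  rows <- lapply(lev, function(g) {
    sub <- R[groups == g, , drop = FALSE]
    complete <- sub[rowSums(is.na(sub)) == 0, , drop = FALSE]
    k <- if (nrow(complete) >= 1L) randolph_kappa(complete, n_categories = 2L)
         else NA_real_
    data.frame(group = g, n_items = nrow(complete), kappa = k,
               stringsAsFactors = FALSE)
  })
  overall <- ratings_matrix(R)
  rows <- c(rows, list(data.frame(group = "overall", n_items = nrow(overall),
                                  kappa = randolph_kappa(overall, 2L),
                                  stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Bootstrap confidence interval for a multi-rater kappa
#'
#' Items (rows) are resampled with replacement and the kappa statistic is
#' recomputed; the percentile interval is reported. Deterministic under
#' `seed`.
#'
#' @param R Ratings matrix (items x raters).
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param statistic Kappa function of a ratings matrix (default
#'   [randolph_kappa()] with 2 categories).
#' @param conf Confidence level.
#' @return A [bootstrap_ci()] `metric_estimate`.
#' @export
kappa_bootstrap_ci <- function(R, n_boot = 10000, seed = 1L,
                               statistic = function(m) randolph_kappa(m, 2L),
                               conf = 0.95) {
  R <- ratings_matrix(R)
  if (nrow(R) < 2L) stopf("need at least 2 items to bootstrap a kappa")
  bootstrap_ci(statistic, R, n_boot = n_boot, seed = seed, conf = conf,
               name = "kappa")
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation between two score vectors, e.g. the
#' AI probability score and the final asbestosis score on escalated cases
#' (which contain ties by construction).
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Tau-b in `[-1, 1]`, or `NA` (with a warning) when either vector
#'   has zero variance.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stopf("need at least 2 observations")
  if (any(is.na(x)) || any(is.na(y))) stopf("missing values in input")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("Kendall tau undefined: zero variance input", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}
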