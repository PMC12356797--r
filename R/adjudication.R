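#' Majority verdict of a three-expert reference panel
#'
#' The reference standard is the majority of three independent expert
#' verdicts: a case is reference-positive iff at least two of the three
#' verdicts are positive. A missing verdict is an error (such cases are
#' excluded upstream rather than imputed).
#'
#' @param verdicts Either a length-3 binary vector (one panel) or an
#'   `n x 3` matrix / data.frame of binary verdicts (one panel per row).
#' @return A single 0/1 verdict, or an integer vector of length `n`.
#' @export
#' @examples
#' adjudicate_panel(c(1, 1, 0)) # 1
#' adjudicate_panel(c(1, 0, 0)) # 0
adjudicate_panel <- function(verdicts) {
  if (is.data.frame(verdicts)) verdicts <- as.matrix(verdicts)
  if (is.matrix(verdicts)) {
    if (ncol(verdicts) != 3L) stopf("a reference panel has exactly 3 verdicts")
    if (any(is.na(verdicts))) {
      stopf("missing reviewer verdict in panel row(s) %s; such cases must be excluded, not imputed",
            paste(which(rowSums(is.na(verdicts)) > 0), collapse = ", "))
    }
    check_binary(verdicts, "verdicts")
    return(as.integer(rowSums(verdicts) >= 2))
  }
  if (length(verdicts) != 3L) stopf("a reference panel has exactly 3 verdicts")
  if (any(is.na(verdicts))) stopf("missing reviewer verdict in panel")
  check_binary(verdicts, "verdicts")
  as.integer(sum(verdicts) >= 2)
}

#' Reference-standard labels for a cohort
#'
#' Applies the majority rule to the three reference verdicts of every case
#' and summarises the distribution of positive verdict counts (0/3 .. 3/3).
#'
#' @param cohort Cohort data.frame with columns `ref_verdict_1..3`.
#' @return A list of class `reference_labels`: `labels` (0/1 per case),
#'   `n_positive`, `n_negative`, and `verdict_count_table` (cases with 0, 1,
#'   2, 3 positive verdicts).
#' @export
reference_labels <- function(cohort) {
  cols <- paste0("ref_verdict_", 1:3)
  stopifnot(is.data.frame(cohort), all(cols %in% names(cohort)))
  v <- as.matrix(cohort[, cols])
  miss <- rowSums(is.na(v)) > 0
  if (any(miss)) {
    stopf("missing reference verdict for case(s) %s",
          paste(cohort$case_id[miss], collapse = ", "))
  }
  labels <- adjudicate_panel(v)
  npos_verdicts <- rowSums(v)
  tab <- vapply(0:3, function(k) sum(npos_verdicts == k), integer(1))
  names(tab) <- paste0(0:3, "/3")
  structure(list(labels = labels,
                 n_positive = sum(labels == 1L),
                 n_negative = sum(labels == 0L),
                 verdict_count_table = tab),
            class = "reference_labels")
}

#' @export
print.reference_labels <- function(x, ...) {
  cat(sprintf("Reference standard: %d positive, %d negative\n",
              x$n_positive, x$n_negative))
  cat("  positive verdicts per panel:",
      paste(sprintf("%s: %d", names(x$verdict_count_table),
                    x$verdict_count_table), collapse = ", "), "\n")
  invisible(x)
}

#' Blinded allocation of reviewers to reference and index panels
#'
#' Emulates the study's pseudorandom reviewer allocation: the reviewer pool
#' is regrouped at fixed intervals (every `period_length` cases, standing in
#' for three-month blocks), an active group of five is drawn from the pool at
#' each boundary, and for every case three of the five are drawn as the
#' reference panel with the remaining two assigned to the index test. All
#' five assignments per case are distinct, and reference/index sets are
#' disjoint by construction. Reviewers are blinded in the sense that
#' assignment is independent of case content.
#'
#' @param case_ids Vector of case identifiers.
#' @param n_pool Reviewer pool size (>= 5, default 13).
#' @param period_length Cases per reallocation block (default 23, roughly a
#'   quarter of a 92-case cohort).
#' @param seed Integer seed; identical seeds reproduce the allocation.
#' @return A data.frame with columns `case_id`, `period`, `ref_1..3`,
#'   `index_1..2` (pool indices).
#' @export
allocate_reviewers <- function(case_ids, n_pool = 13, period_length = 23,
                               seed = 1L) {
  n_pool <- check_count(n_pool, "n_pool", min = 5L)
  period_length <- check_count(period_length, "period_length", min = 1L)
  n <- length(case_ids)
  set.seed(check_count(seed, "seed"))
  period <- ((seq_len(n) - 1L) %/% period_length) + 1L
  out <- matrix(NA_integer_, n, 5L)
  active <- NULL
  current_period <- 0L
  for (i in seq_len(n)) {
    if (period[i] != current_period) {
      active <- sample.int(n_pool, 5L)
      current_period <- period[i]
    }
    draw <- sample(active, 5L)
    out[i, ] <- draw
  }
  data.frame(case_id = case_ids, period = period,
             ref_1 = out[, 1], ref_2 = out[, 2], ref_3 = out[, 3],
             index_1 = out[, 4], index_2 = out[, 5],
             stringsAsFactors = FALSE)
}
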