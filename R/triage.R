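#' Triage thresholds for the AI-driven index test
#'
#' The index test triages the AI asbestosis probability score (0-100) into
#' three categories: scores below `negative_below` are immediately negative,
#' scores at or above `positive_at_or_above` are immediately positive, and
#' the band in between is uncertain and escalates to two independent
#' reviewers. For escalated cases the final asbestosis score (mean of the AI
#' score and the two reviewer verdicts on a common 0-100 scale) is positive
#' at or above `final_positive_at_or_above`.
#'
#' Defaults 35 / 66 / 50 follow the validated assessment procedure; the upper
#' cutoff can be lowered (e.g. to 60) for sensitivity analyses of the
#' automatic acceptance rule. The uncertain band is the half-open interval
#' `[negative_below, positive_at_or_above)`: a score exactly at the upper
#' cutoff is automatically positive.
#'
#' @param negative_below Scores strictly below this are auto-negative
#'   (default 35).
#' @param positive_at_or_above Scores at or above this are auto-positive
#'   (default 66).
#' @param final_positive_at_or_above Final-score threshold for escalated
#'   cases (default 50).
#' @return An object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(negative_below = 35,
                              positive_at_or_above = 66,
                              final_positive_at_or_above = 50) {
  if (!(negative_below >= 0 && negative_below < positive_at_or_above &&
        positive_at_or_above <= 100)) {
    stopf("need 0 <= negative_below < positive_at_or_above <= 100 (got %g, %g)",
          negative_below, positive_at_or_above)
  }
  if (!(final_positive_at_or_above > 0 && final_positive_at_or_above < 100)) {
    stopf("`final_positive_at_or_above` must lie in (0, 100)")
  }
  structure(
    list(negative_below = negative_below,
         positive_at_or_above = positive_at_or_above,
         final_positive_at_or_above = final_positive_at_or_above),
    class = "triage_thresholds"
  )
}

#' @export
print.triage_thresholds <- function(x, ...) {
  cat(sprintf("Triage thresholds: negative < %g <= uncertain < %g <= positive; final score positive >= %g\n",
              x$negative_below, x$positive_at_or_above,
              x$final_positive_at_or_above))
  invisible(x)
}

#' Categorize AI probability scores into triage categories
#'
#' @param ai_score Numeric vector of AI probability scores in `[0, 100]`.
#' @param thresholds A [triage_thresholds()] object.
#' @return Character vector with values `"negative"`, `"uncertain"`,
#'   `"positive"`.
#' @export
#' @examples
#' categorize_score(c(34.9, 35, 65.9, 66, 0, 100))
categorize_score <- function(ai_score, thresholds = triage_thresholds()) {
  stopifnot(inherits(thresholds, "triage_thresholds"))
  if (any(is.na(ai_score))) stopf("`ai_score` contains missing values")
  check_score_range(ai_score)
  ifelse(ai_score < thresholds$negative_below, "negative",
         ifelse(ai_score >= thresholds$positive_at_or_above,
                "positive", "uncertain"))
}

#' Final asbestosis score for escalated cases
#'
#' For a case in the uncertain triage band, the two additional reviewers'
#' binary verdicts are combined with the AI probability score on a common
#' 0-100 scale: `(ai_score + 100 * r1 + 100 * r2) / 3`. A verdict of 1
#' ("positive for asbestosis") contributes 100, a verdict of 0 contributes 0,
#' so the final score is the mean of three assessments expressed as
#' percentages.
#'
#' @param ai_score AI probability score(s), in `[0, 100]`.
#' @param r1,r2 Binary verdicts (0/1) of the two index reviewers.
#' @return Numeric final score(s) in `[0, 100]`, full precision (no rounding
#'   before thresholding).
#' @export
#' @examples
#' final_score(35, 1, 1)   # 78.33
#' final_score(65.9, 0, 0) # 21.97
#' final_score(50, 1, 0)   # exactly 50: positive at the default threshold
final_score <- function(ai_score, r1, r2) {
  check_score_range(ai_score)
  if (any(is.na(ai_score))) stopf("`ai_score` contains missing values")
  if (any(is.na(r1)) || any(is.na(r2))) {
    stopf("escalation incomplete: both index reviewer verdicts are required")
  }
  check_binary(r1, "r1")
  check_binary(r2, "r2")
  (ai_score + 100 * r1 + 100 * r2) / 3
}

#' Run the AI-driven index test on a cohort
#'
#' Applies the full sequential index test to each case: the AI probability
#' score is triaged at the configured cutoffs; auto-negative and
#' auto-positive cases short-circuit to a final verdict without reviewer
#' input; uncertain cases require both index reviewer verdicts, from which
#' the final asbestosis score and the final verdict are computed.
#'
#' If a case has no AI score (e.g. incompatible CT or missing DLCO and no
#' adjusted score on record), a `fallback` hook may supply one: a function
#' taking the case (a one-row data.frame) and returning a score in
#' `[0, 100]`. Without a fallback, such cases are an error naming the missing
#' inputs.
#'
#' @param cohort A cohort data.frame (see [read_cohort()] for the schema).
#' @param thresholds A [triage_thresholds()] object.
#' @param fallback Optional function `(case) -> score` used when `ai_score`
#'   is missing.
#' @return A data.frame with one row per case: `case_id`, `category`,
#'   `final_score` (NA for auto-triaged cases) and `index_verdict` (0/1).
#' @export
run_index_test <- function(cohort, thresholds = triage_thresholds(),
                           fallback = NULL) {
  stopifnot(is.data.frame(cohort))
  score <- cohort$ai_score
  missing_score <- is.na(score)
  if (any(missing_score)) {
    if (is.null(fallback)) {
      stopf("case(s) %s have no AI score (incompatible CT or missing DLCO) and no fallback score hook is configured",
            paste(cohort$case_id[missing_score], collapse = ", "))
    }
    for (i in which(missing_score)) {
      score[i] <- fallback(cohort[i, , drop = FALSE])
    }
    check_score_range(score, "fallback score")
  }
  category <- categorize_score(score, thresholds)
  fs <- rep(NA_real_, nrow(cohort))
  verdict <- integer(nrow(cohort))
  verdict[category == "negative"] <- 0L
  verdict[category == "positive"] <- 1L
  unc <- which(category == "uncertain")
  if (length(unc)) {
    r1 <- cohort$index_verdict_1[unc]
    r2 <- cohort$index_verdict_2[unc]
    if (any(is.na(r1)) || any(is.na(r2))) {
      bad <- unc[is.na(r1) | is.na(r2)]
      stopf("escalation incomplete: uncertain case(s) %s lack two index reviewer verdicts",
            paste(cohort$case_id[bad], collapse = ", "))
    }
    fs[unc] <- final_score(score[unc], r1, r2)
    verdict[unc] <- as.integer(fs[unc] >= thresholds$final_positive_at_or_above)
  }
  data.frame(case_id = cohort$case_id, category = category,
             final_score = fs, index_verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Summarise triage categories and final verdicts of a cohort
#'
#' Tabulates index-test outcomes: cases per triage category, final verdicts
#' within the escalated (uncertain) stratum, and overall approvals/denials,
#' each with its percentage of the cohort (one decimal).
#'
#' @param outcomes Output of [run_index_test()].
#' @return A list of class `triage_summary`: `n`, `categories` (named counts),
#'   `category_pct`, `uncertain_approved`, `uncertain_denied`,
#'   `approved_total`, `denied_total`, and the corresponding percentages.
#' @export
triage_summary <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("category", "index_verdict") %in% names(outcomes)))
  n <- nrow(outcomes)
  lev <- c("negative", "uncertain", "positive")
  counts <- vapply(lev, function(l) sum(outcomes$category == l), integer(1))
  stopifnot(sum(counts) == n)
  unc <- outcomes$category == "uncertain"
  unc_app <- sum(unc & outcomes$index_verdict == 1)
  unc_den <- sum(unc & outcomes$index_verdict == 0)
  pct <- function(k) if (n == 0) 0 else round(100 * k / n, 1)
  structure(list(
    n = n,
    categories = counts,
    category_pct = pct(counts),
    uncertain_approved = unc_app,
    uncertain_denied = unc_den,
    uncertain_approved_pct = pct(unc_app),
    uncertain_denied_pct = pct(unc_den),
    approved_total = sum(outcomes$index_verdict == 1),
    denied_total = sum(outcomes$index_verdict == 0)
  ), class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat(sprintf("Index-test triage of %d cases\n", x$n))
  for (l in names(x$categories)) {
    cat(sprintf("  %-9s %3d (%.1f%%)\n", l, x$categories[[l]],
                x$category_pct[[l]]))
  }
  cat(sprintf("  escalated cases approved: %d (%.1f%%), denied: %d (%.1f%%)\n",
              x$uncertain_approved, x$uncertain_approved_pct,
              x$uncertain_denied, x$uncertain_denied_pct))
  cat(sprintf("  overall: %d approved, %d denied\n",
              x$approved_total, x$denied_total))
  invisible(x)
}
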