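#' Run the full validation pipeline
#'
#' Chains every stage of the prospective-validation analysis on a simulated
#' (or supplied) cohort: triage by the AI-driven index test, adjudication of
#' the three-expert reference standard, diagnostic accuracy metrics with
#' percentile-bootstrap confidence intervals, paired comparison of the
#' ROC-AUC with and without the escalation reviewers, multi-rater agreement
#' (overall, per triage stratum, and the five-reviewer kappa on the
#' escalated stratum), the Kendall tau-b between the AI probability score
#' and the final asbestosis score on escalated cases, and the exact binomial
#' power design. One structured log line per stage reports cases in/out.
#'
#' The report is self-contained: configuration echo, per-stage seeds,
#' package version and timestamp, so an identical configuration and seed
#' reproduce it exactly.
#'
#' @param config A [sim_config()]; ignored when `cohort` is supplied except
#'   as provenance.
#' @param cohort Optional cohort data.frame (e.g. from [read_cohort()]);
#'   when `NULL`, a cohort is simulated from `config`.
#' @param thresholds A [triage_thresholds()] object.
#' @param n_boot Bootstrap iterations for all confidence intervals
#'   (default 10000).
#' @param seed Master seed; per-stage seeds are derived from it
#'   deterministically (default: the configuration seed).
#' @param design Arguments for [design_study()] as a named list; the default
#'   reproduces the one-sided 55-of-59 sensitivity design.
#' @param quiet Suppress per-stage log lines.
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL,
                         thresholds = triage_thresholds(),
                         n_boot = 10000, seed = config$seed,
                         design = list(p_true = 0.98, lower_bound = 0.85,
                                       power_target = 0.99,
                                       ci_method = "one_sided"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  log_stage <- function(...) if (!quiet) message(sprintf(...))

  # -- simulate / load ------------------------------------------------------
  if (is.null(cohort)) {
    cohort <- generate_cohort(config, thresholds)
    log_stage("[simulate] generated %d cases (seed %d)", nrow(cohort),
              config$seed)
  } else {
    validate_cohort(cohort)
    log_stage("[load] %d cases supplied", nrow(cohort))
  }
  n <- nrow(cohort)

  # -- triage ---------------------------------------------------------------
  outcomes <- run_index_test(cohort, thresholds)
  tri <- triage_summary(outcomes)
  log_stage("[triage] %d cases in -> %d negative / %d uncertain / %d positive",
            n, tri$categories[["negative"]], tri$categories[["uncertain"]],
            tri$categories[["positive"]])

  # -- adjudicate -----------------------------------------------------------
  ref <- reference_labels(cohort)
  log_stage("[adjudicate] %d cases in -> %d reference positive / %d negative",
            n, ref$n_positive, ref$n_negative)

  # -- evaluate -------------------------------------------------------------
  seed_metrics <- derive_seed(seed, 101L)
  cc <- confusion(outcomes$index_verdict, ref$labels)
  pm <- point_metrics(cc)
  eval_data <- list(pred = outcomes$index_verdict, ref = ref$labels)
  metric_fns <- list(
    sensitivity = function(d) {
      if (!any(d$ref == 1)) return(NA_real_)
      sum(d$pred == 1 & d$ref == 1) / sum(d$ref == 1)
    },
    specificity = function(d) {
      if (!any(d$ref == 0)) return(NA_real_)
      sum(d$pred == 0 & d$ref == 0) / sum(d$ref == 0)
    },
    accuracy = function(d) mean(d$pred == d$ref),
    ppv = function(d) {
      if (!any(d$pred == 1)) return(NA_real_)
      sum(d$pred == 1 & d$ref == 1) / sum(d$pred == 1)
    },
    npv = function(d) {
      if (!any(d$pred == 0)) return(NA_real_)
      sum(d$pred == 0 & d$ref == 0) / sum(d$pred == 0)
    }
  )
  estimates <- lapply(names(metric_fns), function(nm) {
    bootstrap_ci(metric_fns[[nm]], eval_data, n_boot = n_boot,
                 seed = derive_seed(seed_metrics, match(nm, names(metric_fns))),
                 name = nm)
  })
  names(estimates) <- names(metric_fns)

  # combined score: probability score for auto-triaged cases, final score
  # for escalated ones; the raw probability score is the reviewer-free test
  score_final <- ifelse(is.na(outcomes$final_score), cohort$ai_score,
                        outcomes$final_score)
  auc <- list(
    roc_auc_final = roc_auc(score_final, ref$labels),
    pr_auc_final = pr_auc(score_final, ref$labels),
    roc_auc_score_only = roc_auc(cohort$ai_score, ref$labels),
    pr_auc_score_only = pr_auc(cohort$ai_score, ref$labels)
  )
  roc_ci <- bootstrap_ci(function(d) {
    if (length(unique(d$ref)) < 2) return(NA_real_)
    roc_auc(d$score, d$ref)
  }, list(score = score_final, ref = ref$labels), n_boot = n_boot,
  seed = derive_seed(seed_metrics, 9L), name = "roc_auc")
  auc_test <- compare_auc_paired(score_final, cohort$ai_score, ref$labels)
  log_stage("[evaluate] sensitivity %.3f, specificity %.3f, ROC-AUC %.3f",
            pm[["sensitivity"]], pm[["specificity"]], auc$roc_auc_final)

  # -- agreement ------------------------------------------------------------
  seed_kappa <- derive_seed(seed, 202L)
  ref_mat <- as.matrix(cohort[, paste0("ref_verdict_", 1:3)])
  kap_overall <- kappa_bootstrap_ci(ref_mat, n_boot = n_boot,
                                    seed = seed_kappa)
  strata <- subgroup_kappas(ref_mat, outcomes$category)
  unc <- outcomes$category == "uncertain"
  five_mat <- cbind(ref_mat[unc, , drop = FALSE],
                    as.matrix(cohort[unc, c("index_verdict_1",
                                            "index_verdict_2")]))
  kappa_five <- if (sum(unc) >= 1) randolph_kappa(five_mat, 2L) else NA_real_
  tau <- if (sum(unc) >= 2) {
    kendall_tau(cohort$ai_score[unc], outcomes$final_score[unc])
  } else NA_real_
  log_stage("[agreement] panel kappa %.3f (%d items)",
            kap_overall$point, nrow(ref_mat))

  # -- power design ---------------------------------------------------------
  pd <- do.call(design_study, design)
  log_stage("[power] success criterion %d of %d (power %.4f)",
            pd$k_threshold, pd$n_positives, pd$power_achieved)

  structure(list(
    config = unclass(config),
    thresholds = unclass(thresholds),
    seed = seed,
    n_cases = n,
    triage = list(
      categories = as.list(tri$categories),
      category_pct = as.list(tri$category_pct),
      uncertain_approved = tri$uncertain_approved,
      uncertain_denied = tri$uncertain_denied,
      uncertain_approved_pct = tri$uncertain_approved_pct,
      uncertain_denied_pct = tri$uncertain_denied_pct,
      approved_total = tri$approved_total,
      denied_total = tri$denied_total
    ),
    reference = list(
      n_positive = ref$n_positive,
      n_negative = ref$n_negative,
      verdict_count_table = as.list(ref$verdict_count_table)
    ),
    metrics = list(
      confusion = unclass(cc),
      point = as.list(pm),
      estimates = lapply(estimates, unclass),
      auc = auc,
      roc_auc_ci = unclass(roc_ci),
      auc_comparison = unclass(auc_test),
      seed = seed_metrics,
      n_boot = n_boot
    ),
    agreement = list(
      kappa_reference_panel = unclass(kap_overall),
      kappa_by_stratum = split(strata[, c("n_items", "kappa")],
                               seq_len(nrow(strata))) |>
        stats::setNames(strata$group),
      kappa_five_reviewers_uncertain = kappa_five,
      n_uncertain = sum(unc),
      kendall_tau_uncertain = tau,
      seed = seed_kappa,
      n_boot = n_boot
    ),
    power_design = unclass(pd),
    software_version = as.character(utils::packageVersion("triagedx")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Validation pipeline report (%d cases, seed %d, v%s)\n",
              x$n_cases, x$seed, x$software_version))
  cat(sprintf("  triage: %d negative / %d uncertain / %d positive\n",
              x$triage$categories$negative, x$triage$categories$uncertain,
              x$triage$categories$positive))
  cat(sprintf("  reference standard: %d positive / %d negative\n",
              x$reference$n_positive, x$reference$n_negative))
  pm <- x$metrics$point
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f, ROC-AUC %.3f, PR-AUC %.3f\n",
              pm$sensitivity, pm$specificity, pm$accuracy,
              x$metrics$auc$roc_auc_final, x$metrics$auc$pr_auc_final))
  cat(sprintf("  panel kappa %.3f; five-reviewer kappa (uncertain) %.3f; tau-b %.3f\n",
              x$agreement$kappa_reference_panel$point,
              x$agreement$kappa_five_reviewers_uncertain,
              x$agreement$kendall_tau_uncertain))
  cat(sprintf("  power design: %d of %d (power %.4f)\n",
              x$power_design$k_threshold, x$power_design$n_positives,
              x$power_design$power_achieved))
  invisible(x)
}
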