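# triagedx

Validation tooling for **AI-plus-human sequential triage** in diagnostic
compensation settings, built around the asbestosis use case: an AI
probability score `s ∈ [0, 100]` triages each applicant into auto-negative
(`s < 35`), auto-positive (`s ≥ 66`) or uncertain; uncertain cases escalate
to two independent expert reviewers whose binary verdicts are averaged with
the score on a common scale,

    f = (s + 100·r1 + 100·r2) / 3,

with a final positive verdict iff `f ≥ 50`. The procedure is validated
against a reference standard — the majority verdict of a blinded
three-pulmonologist panel — using diagnostic accuracy metrics with
percentile-bootstrap confidence intervals, paired correlated ROC-AUC
comparison (DeLong), multi-rater agreement (free-marginal Randolph kappa,
Fleiss kappa, subgroup kappas, Kendall tau-b), and an exact binomial power
design for one-sided sensitivity validation: recruit until `n`
reference-positive cases, succeed iff at least `k = max{k : P(X ≥ k) ≥
power}` are index-positive, with `X ~ Bin(n, p_anticipated)` and a
Clopper–Pearson lower bound on `k/n` at or above the required sensitivity
floor.

Because applicant-level data are not public, the package includes a
calibrated synthetic cohort generator (class-conditional Beta scores,
correlated binary raters via a latent-trait model, MCAR missingness flags)
so the entire pipeline is testable end to end. It is aimed at
biostatisticians and methods researchers designing or auditing human-AI
deferral procedures in diagnostic accuracy studies.

## Worked example

```r
library(triagedx)

cfg <- sim_config(n_cases = 92, seed = 7)   # calibrated defaults
report <- run_pipeline(cfg, n_boot = 2000)
```

```
[simulate] generated 92 cases (seed 7)
[triage] 92 cases in -> 8 negative / 59 uncertain / 25 positive
[adjudicate] 92 cases in -> 60 reference positive / 32 negative
[evaluate] sensitivity 0.950, specificity 0.719, ROC-AUC 0.919
[agreement] panel kappa 0.594 (92 items)
[power] success criterion 55 of 59 (power 0.9935)
```

The triage line is the deferral bookkeeping: 8 applicants auto-denied by the
score alone, 25 auto-approved, 59 escalated to two reviewers. The evaluate
line compares final index verdicts with the panel majority — here 57 of 60
reference positives were index-positive (sensitivity 0.950, 95% bootstrap CI
0.889–1.000). The agreement line is the free-marginal kappa of the
three-rater panel (chance fixed at 0.5): 0.594, moderate agreement, which
bounds how well any index test can look against this reference standard.

The design that sized the study:

```r
design_study(p_true = 0.98, lower_bound = 0.85, power_target = 0.99,
             ci_method = "one_sided")
```

```
Exact binomial sensitivity-validation design
  anticipated sensitivity 0.980, power target 0.99, lower bound 0.85 (one-sided Clopper-Pearson, alpha 0.05)
  success criterion: 55 of 59 reference positives correctly classified
  point sensitivity at criterion: 93.2%; achieved power 0.9935; CI for k/n: 0.852-1.000
```

That is: with 59 reference positives, a procedure whose true sensitivity is
98% passes the 55-of-59 bar with probability 0.9935, and 55/59 = 93.2% still
carries a one-sided 95% lower confidence bound of 85%.

Individual pieces are exported separately — `categorize_score()`,
`final_score()`, `run_index_test()`, `adjudicate_panel()`,
`allocate_reviewers()`, `confusion()` / `point_metrics()`, `roc_auc()` /
`pr_auc()` / `bootstrap_ci()` / `compare_auc_paired()`, `randolph_kappa()` /
`fleiss_kappa()` / `subgroup_kappas()` / `kendall_tau()`, `exact_power()` /
`max_threshold()` / `clopper_pearson()` / `design_study()` — along with CSV
/ YAML / JSON readers and writers (`read_cohort()`, `read_sim_config()`,
`write_report()`) and a thin command-line wrapper in `inst/cli/triagedx.R`.
See the vignette in `vignettes/validating-ai-triage.Rmd` for the model,
calibration and design choices.

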