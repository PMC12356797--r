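---
title: "Validating an AI-plus-human sequential triage procedure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an AI-plus-human sequential triage procedure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagedx)
```

## The assessment procedure

`triagedx` models a sequential human-AI assessment used to adjudicate
asbestosis compensation claims. Each applicant carries an AI-derived
asbestosis probability score $s \in [0, 100]$, combining a CT classifier
output with the DLCO lung-function measure. The index test triages the score
at two cutoffs:

* $s < 35$: automatically negative;
* $s \ge 66$: automatically positive;
* $35 \le s < 66$: uncertain — the case is escalated to two independent
  expert reviewers.

For escalated cases the reviewers' binary verdicts $r_1, r_2 \in \{0, 1\}$
are combined with the score on a common 0–100 scale into the final
asbestosis score

$$f = \frac{s + 100\,r_1 + 100\,r_2}{3},$$

and the index verdict is positive iff $f \ge 50$. The reference standard is
the majority verdict of a separate three-expert panel (positive iff at least
two of three verdicts are positive), with all five reviewers drawn blindly
from a pool of thirteen and reallocated periodically.

Two consequences of the final-score algebra are worth keeping in mind (both
are asserted exhaustively in the test suite over a dense grid of the
uncertain band):

* **Unanimity dominates.** If both reviewers agree, their verdict decides:
  the minimum of $f$ with $r_1 = r_2 = 1$ is $(35 + 200)/3 \approx 78.3 \ge 50$,
  and the maximum with $r_1 = r_2 = 0$ is $66/3 = 22 < 50$.
* **Split reviewers defer to the AI.** With $r_1 \ne r_2$,
  $f = (s + 100)/3 \ge 50 \iff s \ge 50$, so the verdict reduces to
  thresholding the AI score at 50.

### Boundary and scale conventions

The triage band description ("35–66 uncertain") and the automatic acceptance
rule ("positive if $\ge 66.0$") overlap at exactly 66; the operational rule
is the more precise statement, so the uncertain band is the half-open
interval $[35, 66)$ and a score of exactly 66 is automatically positive.
Reviewer verdicts are defined on a 0/1 scale while the score and the final
threshold live on 0–100; entering the verdicts into the mean verbatim as 0
or 1 would make the reviewers numerically irrelevant, so they are mapped to
the common 0–100 scale (0 or 100). The test suite verifies that computing
everything on a 0–1 scale instead yields identical verdicts. Final scores
are kept at full precision; comparisons use exact `>=` with no rounding
before thresholding.

Applicants whose CT is incompatible with the classifier or whose DLCO is
missing received an adjusted score in the original procedure via an
alternative formula that is not publicly specified. `run_index_test()`
exposes this as a pluggable `fallback` hook (a function from a case record
to a score); without a hook such cases are an explicit error. The package
deliberately does not invent the unpublished formula.

## The power design

The validation was designed around a one-sided sensitivity target: with an
anticipated sensitivity of 0.98, the study recruits until $n$
reference-positive cases are observed and declares success iff at least $k$
of them are index-positive. `exact_power(n, k, p)` is the exact binomial
tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n, p)$; `max_threshold(n, p, t)` is
the strictest criterion retaining power $t$; and `design_study()` scans $n$
upward (an exact linear scan, capped at `n_max = 10000`) until the
Clopper–Pearson lower bound for $k/n$ reaches the required 0.85.

The interval convention matters. For $k = 55$, $n = 59$ the one-sided 95%
Clopper–Pearson lower bound is 0.852 while the two-sided bound is 0.835, and
the smallest $n$ whose design clears 0.85 is 59 under the one-sided
convention versus 75 under the two-sided. Because the stated test is
one-sided, the package treats the one-sided convention as the one that
reproduces the published 55-of-59 design (point sensitivity 93%, exact power
0.9935); `clopper_pearson()` and `design_study()` nevertheless default to
the more conservative two-sided convention, and every design object records
which convention produced it.

## Statistics

* **Accuracy metrics.** `point_metrics()` computes sensitivity, specificity,
  accuracy, PPV and NPV from a 2×2 table; zero-denominator metrics are `NA`,
  never silently 0. `roc_auc()` is the rank-based Mann–Whitney estimator with
  half credit for ties (invariant under monotone score transforms);
  `pr_auc()` is average precision with step interpolation — trapezoidal
  interpolation between PR points is optimistic and deliberately avoided.
* **Confidence intervals.** `bootstrap_ci()` implements the percentile
  bootstrap: cases are resampled with replacement (10,000 iterations by
  default), the statistic is recomputed, and the 2.5th/97.5th percentiles
  reported. Resamples on which a statistic is undefined (e.g. no
  reference-positive case drawn) are skipped and counted in the estimate's
  provenance rather than silently dropped; an all-degenerate bootstrap is an
  error. BCa corrections are not used. Every estimate carries its seed.
* **Correlated AUC comparison.** The published analysis compared the ROC-AUC
  of the full procedure against the reviewer-free score with a correction
  for correlated assessments whose exact form is not public.
  `compare_auc_paired()` provides DeLong's placement-value method as the
  documented stand-in, with a paired case-resampling bootstrap as an
  alternative; both account for the shared cases.
* **Agreement.** `randolph_kappa()` is the free-marginal multi-rater kappa,
  $(\bar P_o - 1/c)/(1 - 1/c)$ with the chance of agreeing on a binary
  diagnosis fixed at 0.5 regardless of the observed verdict marginals;
  `fleiss_kappa()` is the marginal-dependent contrast. Items with a missing
  rating are excluded listwise and counted, matching the study's handling of
  its one incomplete panel; nothing is imputed. Subgroup kappas stratify by
  triage category, and the five-reviewer kappa on the uncertain stratum
  pools the reference panel with the two escalation reviewers.
  `kendall_tau()` is tau-b, since final scores contain ties by construction.
  The published kappa p-values come from an unnamed test; the package
  reports bootstrap confidence intervals only.
* **Kendall tau stratum.** The pipeline computes tau between the probability
  score and the final score on the uncertain stratum only: outside it the
  final score is not defined (auto-triaged cases never receive one), and the
  published moderate correlation is only plausible on the escalated cases.

## The synthetic cohort generator

No applicant-level data are public, so the generator is the package's test
bed. It emulates the statistical structure the analysis assumes, with
defaults calibrated once to the study-level aggregates:

* **Cohort**: 92 cases, prevalence 0.62 (57 of 92 reference positives).
* **Scores**: class-conditional scaled Betas, positives
  $100 \cdot \mathrm{Beta}(16.61, 10.06)$, negatives
  $100 \cdot \mathrm{Beta}(6.87, 8.49)$. These were solved numerically from
  three constraints — marginal triage fractions 8.7% / 67.4% / 23.9% at the
  35/66 cutoffs and a class-separation ROC-AUC of 0.87 — with a cap on Beta
  concentration so neither class collapses to a near-degenerate spike.
  Bounded support matches a probability score defined on 0–100; any other
  Beta parameters may be supplied.
* **Raters**: a shared standard-normal latent difficulty per case plus
  independent rater noise, thresholded so each rater's marginal
  sensitivity/specificity match the configuration exactly while
  `latent_correlation` tunes within-case dependence. Defaults
  (se 0.88, sp 0.85, correlation 0.2) imply a three-rater free-marginal
  kappa of about 0.585, matching the published panel kappa of 0.59. The
  study reports no per-rater error rates or correlation structure, so these
  defaults are conventions chosen to hit the aggregate targets, not
  estimates.
* **Missingness**: CT-incompatibility and missing-DLCO flags are missing
  completely at random at rates 3/92 and 5/92 — the study reports only
  counts, not a mechanism. Flags are metadata: synthetic scores are still
  generated (the real procedure substituted an adjusted score).
* **Reproducibility**: each case derives its own RNG substream from the
  configuration seed, so record $i$ is identical whether 20 or 20,000 cases
  are generated, and a CSV round trip preserves the cohort bit-for-bit.

What the generator does **not** emulate: demographics and their association
with disease, reviewer identity effects (all raters share one error model),
informative missingness, reapplications, or any image-level structure. Tests
passing on synthetic cohorts therefore validate the statistical machinery
and the procedure's algebra, not the clinical performance claims — the
published real-data confidence intervals, AUCs and subgroup kappas cannot be
reproduced without the data and are covered instead by property-based tests
and calibration checks.

## Reviewer allocation

The published allocation used a pre-established draw decision tree with
reviewers regrouped every three months; the tree itself is not public.
`allocate_reviewers()` models its described properties abstractly: at each
period boundary (periods are counted in cases, default 23 — the simulator
has no calendar) an active group of five is drawn from the pool, and for
each case three of the five are drawn as the reference panel with the
remaining two assigned to the index test. Reference and index sets are
disjoint by construction, and each of 13 pool members serves on the
reference panel for 3/13 of cases in expectation.

## Numerical choices and problem sizes

Exact binomial tails are summed from the smallest term upward; the design
search is a linear scan (exactness over speed). Bootstrap percentile
endpoints use the default quantile estimator. Ties in ROC ranks get half
credit. The test suite exercises Monte-Carlo checks at sizes chosen to keep
tolerances honest: marginal recovery at n = 10,000 cohorts, rater-parameter
recovery at n = 5,000, triage-fraction calibration over 1,000 cohorts of 92,
and percentile-CI coverage over 500 simulated cohorts with 2,000 bootstrap
iterations each — a characterisation at 2,000 cohorts put the true coverage
near 94%, within the expected slight undercoverage of the percentile
bootstrap for a proportion at this sample size.

## Known limitations

* The unpublished adjusted-score formula, draw decision tree and correlated
  AUC correction are represented by a hook, an abstract scheme and DeLong's
  method respectively; none claims to replicate the originals.
* The published accuracy of 0.87 is not exactly recoverable from a single
  confusion table consistent with the other printed metrics (reconstructions
  give 0.86–0.87 depending on rounding); the package reproduces the
  sensitivity reconstruction (49/57 = 0.86) and leaves the discrepancy
  noted.
* Percentile bootstrap intervals for proportions at n = 92 undercover
  slightly (~94% for a nominal 95%); this is a property of the method the
  study used, not a defect of the implementation.
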