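{
  "schema_version": "1.0",
  "description": "Structural schema for triagedx run_pipeline() reports. Every stochastic stage must carry the seed that produced it.",
  "required_top_level": ["config", "thresholds", "seed", "n_cases",
                         "software_version", "timestamp"],
  "required_stages": {
    "triage": ["categories", "category_pct", "uncertain_approved",
               "uncertain_denied", "approved_total", "denied_total"],
    "reference": ["n_positive", "n_negative", "verdict_count_table"],
    "metrics": ["confusion", "point", "estimates", "auc", "auc_comparison",
                "seed", "n_boot"],
    "agreement": ["kappa_reference_panel", "kappa_by_stratum",
                  "kappa_five_reviewers_uncertain", "kendall_tau_uncertain",
                  "seed", "n_boot"],
    "power_design": ["n_positives", "k_threshold", "point_sensitivity",
                     "power_achieved", "ci"]
  }
}
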