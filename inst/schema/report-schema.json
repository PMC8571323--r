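{
  "title": "rab5atools pipeline report",
  "required": ["schema_version", "seed", "marker", "arms", "stages"],
  "stages": {
    "cohort": ["n", "arm_sizes", "pcr_by_arm"],
    "qualify": ["table_file", "marker_p_by_model"],
    "threshold_cv": ["threshold", "source"],
    "balance": ["threshold", "hr_fisher_p", "erbb2_rank_p", "mosaic_file"],
    "bayes": [],
    "roc": [],
    "invitro": ["r2", "slope", "intercept", "n_lines"],
    "allred": ["n", "n_high", "n_low", "U", "p", "medians"]
  }
}
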