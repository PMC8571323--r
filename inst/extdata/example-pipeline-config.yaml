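# Example configuration for rab5atools::run_pipeline() /
# inst/scripts/run_pipeline.R. Any omitted field keeps its default.
seed: 1
outdir: pipeline-out
stages: [simulate, qualify, threshold_cv, balance, bayes, roc, invitro, allred]
marker: RAB5A
arms: [TDM1P, TH]
# threshold_override: 9.76   # skip the CV search and use this threshold
cohort_sim:
  n_per_arm: {TDM1P: 52, TH: 31, THP: 44}
  biomarker_mean: {TDM1P: 10.35, TH: 11.0, THP: 10.5}
  biomarker_sd: 0.8
cv:
  n_iterations: 100
bayes:
  n_keep: 10000
  n_adapt: 1000
  n_burnin: 5000
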