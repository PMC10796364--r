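# Example pipeline configuration; see parse_config() for the schema and
# defaults. Run e.g.:
#   Rscript inst/scripts/nitjm.R simulate,preprocess,fit-joint,evaluate,compare \
#     --config inst/extdata/example_config.yaml
seed: 1
paths:
  output_dir: nitjm_output
simulate:
  n_patients: 300
model:
  baseline: [cerebral_oedema, cerebral_infarction, respiratory_failure,
             hydrocephalus, vasospasm]
  dynamic: [gcs, wbc_abnormal, hyperglycemia]
  mode: both
mcmc:
  chains: 2
  iter: 2000
  warmup: 1000
evaluation:
  Ts_list: [1, 2, 3, 5, 7]
  dt_list: [1, 2, 3, 5, 7]
  n_theta: 20
  n_b_draws: 150
  n_burn: 150
thresholds:
  - {covariate: glucose, kind: at_least, cutoff: 126, output_name: hyperglycemia}
  - {covariate: spo2, kind: below, cutoff: 95, output_name: low_spo2}
  - {covariate: wbc, kind: outside_band, lower: 4, upper: 12, output_name: wbc_abnormal}
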