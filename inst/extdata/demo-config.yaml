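## Demonstration configuration for `run_all()` / `uvhotspot run-all`.
## A small cohort so the full pipeline finishes in seconds; see
## ?damage_params and ?simulate_cohort for every tunable default.
seed: 7
cohort:
  n_sites: 40
  region_length: 720
  bound_fraction: 0.65
damage:
  sequencing_depth: 21600
dnase:
  target_rho: 0.41
classify:
  fold_threshold: 2.0
  abs_threshold: 50
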