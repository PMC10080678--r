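{
  "experiment_id": "EXP013",
  "sigma_mM": 5.75,
  "step_rate_s": [30, 60, 120],
  "formaldehyde_in_mM": 50,
  "dha_in_mM": 50,
  "ca_in_mean_mM": 15,
  "reactor": {
    "volume_uL": 411,
    "residence_time_s": 120,
    "temperature_C": 21
  },
  "stocks": {
    "formaldehyde": 198,
    "dha": 198,
    "naoh": 240,
    "cacl2": 120
  },
  "sampling": {
    "start_s": 1800,
    "interval_s": 30.6,
    "n_samples": 50
  },
  "equilibration_s": 1800,
  "seed": 1,
  "noise_cv": 0.05
}
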