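{
  "schema_version": 1,
  "master_seed": 1,
  "n": 16305,
  "truncation": "quantile",
  "gcs_split": "bernoulli",
  "welch": false,
  "scenarios": ["equal", "unequal", "swap-equal", "swap-unequal"]
}
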