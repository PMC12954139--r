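{
  "level": 0.975,
  "cutoff": 1.1440,
  "lower_cutoff": null,
  "n_source": 857,
  "quantile_rule": "empirical percentile (as published)",
  "label": "published (EMINCA subgroup A, n = 857)"
}
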