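{
  "a": 2.7895,
  "b": 0.0326,
  "x": 0.0526,
  "y": 2.1659,
  "label": "published (EMINCA subgroup A, n = 857)"
}
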