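{
  "seed": 7,
  "S": 80,
  "simulate": {
    "cancer_types": ["adenoca_A", "squamous_C"],
    "samples_per_type": 6,
    "n_segments": 8,
    "draws_S": 80
  }
}
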