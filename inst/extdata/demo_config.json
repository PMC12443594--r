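{
  "seed": 1,
  "outdir": "esc_results",
  "locus": { "n_v": 3, "n_j": 2, "kde": true },
  "population": {
    "n_founders": 12,
    "divisions": 6,
    "esc_replication_prob": 0.5,
    "segregation": "binomial"
  },
  "wgs": { "circle_coverage": 20, "genome_coverage": 2 },
  "lam": { "max_mismatch": 1, "min_identity": 0.9, "min_span": 50 },
  "sv": {
    "n_sv": 40,
    "proportions": { "none": 0.5, "single": 0.35, "double": 0.15 },
    "window": 50,
    "threshold": 15
  }
}
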