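{
  "structure": "total",
  "cutpoint_gy": 12,
  "mean_gland_dose": {"below": 24.5, "above": 30.9},
  "groups": {
    "timepoint": ["6mo", "6mo", "12mo", "12mo"],
    "group": ["below", "above", "below", "above"],
    "n_toxic": [6, 11, 4, 8],
    "n_total": [19, 14, 18, 11]
  }
}
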