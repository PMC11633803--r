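{
  "structure": "ig",
  "cutpoint_gy": 14,
  "mean_gland_dose": {"below": 24.6, "above": 31.2},
  "groups": {
    "timepoint": ["6mo", "6mo", "12mo", "12mo"],
    "group": ["below", "above", "below", "above"],
    "n_toxic": [5, 12, 4, 8],
    "n_total": [19, 14, 18, 11]
  }
}
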