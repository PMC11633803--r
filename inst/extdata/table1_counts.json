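{
  "t_stage": {
    "rows": ["T0-T1", "T2-T3", "T4"],
    "cols": ["PDS", "PGS"],
    "counts": [[11, 37], [23, 71], [4, 0]]
  },
  "n_stage": {
    "rows": ["N0-N2a", "N2b", "N2c", "N3"],
    "cols": ["PDS", "PGS"],
    "counts": [[7, 23], [22, 67], [7, 18], [2, 0]]
  },
  "prescription": {
    "rows": ["60Gy", "70Gy"],
    "cols": ["PDS", "PGS"],
    "counts": [[28, 108], [10, 0]]
  }
}
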