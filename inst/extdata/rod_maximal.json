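{
  "elastics": {
    "A": {"epsilon": 0.70710678118654752, "d": 0},
    "Ap": {"epsilon": 0.70710678118654752, "d": 0},
    "B": {"epsilon": 0.70710678118654752, "d": 0},
    "Bp": {"epsilon": 0.70710678118654752, "d": 0}
  },
  "orientations": {
    "A": 0,
    "Ap": 1.5707963267948966,
    "B": 0.78539816339744831,
    "Bp": 2.3561944901923449
  },
  "order_policy": "uniform-mix"
}
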