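{
  "n_states": 2,
  "n_outcomes": 2,
  "n_actions": 2,
  "horizon": 1,
  "A": [
    [1, 0],
    [0, 1]
  ],
  "B": [
    [
      [0, 1],
      [1, 0]
    ],
    [
      [1, 0],
      [0, 1]
    ]
  ],
  "D": [0.5, 0.5],
  "C": {
    "log_probs": [
      [-36.8413614879047, 0]
    ]
  },
  "policies": [
    [1],
    [2]
  ],
  "gamma": 1,
  "E": [
    [0.5, 0.5],
    [0.5, 0.5]
  ],
  "E_counts": [
    [1, 1],
    [1, 1]
  ]
}
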