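{
  "label": ["inferior", "septum", "lateral", "posterior", "anterior"],
  "alpha": [
    [0, 1],
    [0.75, 1],
    [0, 0.25],
    [0.25, 0.75],
    [0.25, 0.75]
  ],
  "beta": [
    [0, 0.2],
    [0.2, 1],
    [0.2, 1],
    [0.55, 1],
    [0.2, 0.55]
  ]
}
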