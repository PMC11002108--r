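{
  "alpha": [0, 0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 1],
  "beta": [0, 0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 1],
  "theta": [
    [0, 0, 0, 0, 0, -0, -0, -0, -0],
    [0.400745153256231, 0.370240244846531, 0.283369615395123, 0.153358530751768, 2.45385634604529e-17, -0.153358530751768, -0.283369615395123, -0.370240244846531, -0.400745153256231],
    [0.740480489693061, 0.684114768651354, 0.523598775598299, 0.283369615395123, 4.53413530766836e-17, -0.283369615395123, -0.523598775598299, -0.684114768651354, -0.740480489693061],
    [0.967484384046477, 0.893839020444829, 0.684114768651354, 0.370240244846531, 5.92413327073783e-17, -0.37024024484653, -0.684114768651354, -0.893839020444829, -0.967484384046477],
    [1.0471975511966, 0.967484384046477, 0.740480489693061, 0.400745153256231, 6.4122356457393e-17, -0.400745153256231, -0.740480489693061, -0.967484384046477, -1.0471975511966],
    [0.967484384046477, 0.893839020444829, 0.684114768651354, 0.370240244846531, 5.92413327073783e-17, -0.37024024484653, -0.684114768651354, -0.893839020444829, -0.967484384046477],
    [0.740480489693061, 0.684114768651354, 0.523598775598299, 0.283369615395123, 4.53413530766836e-17, -0.283369615395123, -0.523598775598299, -0.684114768651354, -0.740480489693061],
    [0.400745153256231, 0.370240244846531, 0.283369615395123, 0.153358530751768, 2.45385634604529e-17, -0.153358530751768, -0.283369615395123, -0.370240244846531, -0.400745153256231],
    [1.28244712914786e-16, 1.18482665414757e-16, 9.06827061533672e-17, 4.90771269209059e-17, 7.85272385893319e-33, -4.90771269209059e-17, -9.06827061533672e-17, -1.18482665414757e-16, -1.28244712914786e-16]
  ],
  "note": ["synthetic smoothly varying atlas; not measured human fibre data"]
}
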