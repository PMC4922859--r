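{
  "name": "type3_capacitor",
  "description": "Ready-made capacitor system: a stable 3-node Jacobian whose non-diffusible node has a positive self-rate, so the dispersion relation stays positive in the q -> infinity limit and the instability holds for every combination of positive diffusion coefficients.",
  "labels": ["v", "w", "u"],
  "J": [[-1.0, 0.0, 2.0], [0.0, -1.0, 2.0], [-1.0, -0.5, 0.25]],
  "D": [0.3, 0.7, 0.0]
}
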