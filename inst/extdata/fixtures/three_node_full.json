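{
  "name": "three_node_full",
  "description": "Unconstrained catalog of minimal 3-node networks: two diffusible signals (v, w) and one cell-autonomous factor (u), six interactions.",
  "nodes": [
    {"label": "v", "diffusible": true},
    {"label": "w", "diffusible": true},
    {"label": "u", "diffusible": false}
  ],
  "k": 6
}
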