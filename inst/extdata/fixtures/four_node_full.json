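{
  "name": "four_node_full",
  "description": "Unconstrained catalog of minimal 4-node networks: two diffusible signals (v, w) and two cell-autonomous factors (u, z), seven interactions.",
  "nodes": [
    {"label": "v", "diffusible": true},
    {"label": "w", "diffusible": true},
    {"label": "u", "diffusible": false},
    {"label": "z", "diffusible": false}
  ],
  "k": 7
}
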