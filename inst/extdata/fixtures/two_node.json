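{
  "name": "two_node",
  "description": "Classical two-node control: the complete 2-node network whose two surviving phase classes are the activator-inhibitor (in-phase) and substrate-depleted (out-of-phase) systems.",
  "nodes": [
    {"label": "v", "diffusible": true},
    {"label": "w", "diffusible": true}
  ],
  "k": 4
}
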