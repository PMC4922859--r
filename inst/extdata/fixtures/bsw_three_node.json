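{
  "name": "bsw_three_node",
  "description": "Three-node BMP/Sox9/Wnt digit-patterning screen: diffusible BMP (B) and Wnt (W), non-diffusible transcription factor Sox9 (S9). Known regulation: BMP promotes Sox9, Wnt inhibits Sox9; both signals decay; Sox9 peaks out-of-phase of BMP and Wnt.",
  "nodes": [
    {"label": "B", "diffusible": true},
    {"label": "W", "diffusible": true},
    {"label": "S9", "diffusible": false}
  ],
  "k": 6,
  "constraints": {
    "forced_edges": [
      {"target": "S9", "source": "B"},
      {"target": "S9", "source": "W"},
      {"target": "B", "source": "B"},
      {"target": "W", "source": "W"}
    ],
    "sign_constraints": [
      {"target": "S9", "source": "B", "sign": 1},
      {"target": "S9", "source": "W", "sign": -1},
      {"target": "B", "source": "B", "sign": -1},
      {"target": "W", "source": "W", "sign": -1}
    ],
    "phase_constraints": [
      {"a": "S9", "b": "B", "relation": "out-of-phase"},
      {"a": "S9", "b": "W", "relation": "out-of-phase"},
      {"a": "B", "b": "W", "relation": "in-phase"}
    ]
  }
}
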