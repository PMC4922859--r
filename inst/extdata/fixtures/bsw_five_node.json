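{
  "name": "bsw_five_node",
  "description": "Five-node digit-patterning screen: diffusible BMP (B) and Wnt (W); non-diffusible pSmad1/5/8 (Sm), beta-catenin (bc) and Sox9 (S9). Known interactions are forced (BMP signals through pSmad, Wnt through beta-catenin, pSmad promotes Sox9, beta-catenin inhibits signaling through pSmad, Sox9 feeds back on Wnt, pSmad feeds back on BMP, both signals decay); one candidate interaction is screened. Phases reflect the experimental patterns: Sox9 out-of-phase of BMP expression and Wnt activity, BMP expression out-of-phase of its own signaling.",
  "nodes": [
    {"label": "B", "diffusible": true},
    {"label": "W", "diffusible": true},
    {"label": "Sm", "diffusible": false},
    {"label": "bc", "diffusible": false},
    {"label": "S9", "diffusible": false}
  ],
  "k": 9,
  "constraints": {
    "forced_edges": [
      {"target": "Sm", "source": "B"},
      {"target": "S9", "source": "Sm"},
      {"target": "bc", "source": "W"},
      {"target": "Sm", "source": "bc"},
      {"target": "W", "source": "S9"},
      {"target": "B", "source": "Sm"},
      {"target": "B", "source": "B"},
      {"target": "W", "source": "W"}
    ],
    "sign_constraints": [
      {"target": "Sm", "source": "B", "sign": 1},
      {"target": "S9", "source": "Sm", "sign": 1},
      {"target": "bc", "source": "W", "sign": 1},
      {"target": "Sm", "source": "bc", "sign": -1},
      {"target": "W", "source": "S9", "sign": -1},
      {"target": "B", "source": "Sm", "sign": -1},
      {"target": "B", "source": "B", "sign": -1},
      {"target": "W", "source": "W", "sign": -1}
    ],
    "phase_constraints": [
      {"a": "S9", "b": "B", "relation": "out-of-phase"},
      {"a": "S9", "b": "bc", "relation": "out-of-phase"},
      {"a": "B", "b": "Sm", "relation": "out-of-phase"}
    ]
  }
}
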