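{
  "name": "nodal_lefty",
  "description": "Extended Nodal/Lefty screen: the two-signal activator-inhibitor system plus a cell-autonomous signaling node S (pSmad2/3). Constraints: positive Nodal/signaling feedback loop, signaling-induced Lefty expression, negative self-edges on Nodal and Lefty (clearance; fix their rates via value_constraints to use measured clearance rate constants), Lefty acts as an inhibitor wherever its outgoing edge lands, and Nodal/Lefty patterns must be in-phase (overlapping expression domains).",
  "nodes": [
    {"label": "N", "diffusible": true},
    {"label": "L", "diffusible": true},
    {"label": "S", "diffusible": false}
  ],
  "k": 6,
  "constraints": {
    "forced_edges": [
      {"target": "N", "source": "S"},
      {"target": "S", "source": "N"},
      {"target": "L", "source": "S"},
      {"target": "N", "source": "N"},
      {"target": "L", "source": "L"}
    ],
    "sign_constraints": [
      {"target": "N", "source": "S", "sign": 1},
      {"target": "S", "source": "N", "sign": 1},
      {"target": "L", "source": "S", "sign": 1},
      {"target": "N", "source": "N", "sign": -1},
      {"target": "L", "source": "L", "sign": -1},
      {"target": "N", "source": "L", "sign": -1},
      {"target": "S", "source": "L", "sign": -1}
    ],
    "phase_constraints": [
      {"a": "N", "b": "L", "relation": "in-phase"}
    ]
  }
}
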