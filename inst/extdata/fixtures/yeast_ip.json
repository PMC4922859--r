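{
  "name": "yeast_ip",
  "description": "Synthetic yeast cytokinin (IP) circuit screen: extend the engineered positive feedback (hormone w activates receptor signaling u, which drives synthase z, which produces w) with a second diffusible hormone v so the 4-node, 7-edge circuit forms a reaction-diffusion pattern. Diffusible hormones interact only through cell-autonomous factors; self-edges on hormones are inhibitory (decay); the receptor-signaling node is activated only by its ligands (its self-edge and a synthase input are excluded), all other candidate interactions being transcriptional.",
  "nodes": [
    {"label": "w", "diffusible": true},
    {"label": "v", "diffusible": true},
    {"label": "u", "diffusible": false},
    {"label": "z", "diffusible": false}
  ],
  "k": 7,
  "constraints": {
    "forced_edges": [
      {"target": "u", "source": "w"},
      {"target": "z", "source": "u"},
      {"target": "w", "source": "z"}
    ],
    "forbidden_edges": [
      {"target": "u", "source": "u"},
      {"target": "u", "source": "z"}
    ],
    "sign_constraints": [
      {"target": "u", "source": "w", "sign": 1},
      {"target": "z", "source": "u", "sign": 1},
      {"target": "w", "source": "z", "sign": 1}
    ],
    "no_diffusible_to_diffusible": true,
    "diffusible_self_inhibition": true
  }
}
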