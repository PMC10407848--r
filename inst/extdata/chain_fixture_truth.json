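{
  "seed": 1,
  "n_atoms": 204,
  "relay_resnums": [252, 289, 249, 265],
  "relay_labels": ["GLU252", "GLU289", "SER249", "ASP265"],
  "spacings": [3.4, 3.5, 4.1, 5.2],
  "anchor_point": [0, 0, 0],
  "synthetic": true,
  "description": "synthetic planted-relay structure emitted by generate_relay_structure(relay_structure_spec(seed = 1))"
}
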