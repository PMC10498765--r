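{
  "schema": "ffru-tree/1",
  "units": { "length": "mm" },
  "root": "LM",
  "segments": [
    { "id": "LM", "length": 10, "d_prox": 4.0, "d_dist": 3.8 },
    { "id": "LAD", "parent": "LM", "length": 40, "d_prox": 3.2, "d_dist": 2.2 },
    { "id": "LCX", "parent": "LM", "length": 35, "d_prox": 2.8, "d_dist": 2.0 },
    { "id": "LAD_d", "parent": "LAD", "length": 30, "d_prox": 1.8, "d_dist": 1.4 },
    { "id": "D1", "parent": "LAD", "length": 25, "d_prox": 1.6, "d_dist": 1.2 },
    { "id": "OM1", "parent": "LCX", "length": 22, "d_prox": 1.5, "d_dist": 1.1 },
    { "id": "LCX_d", "parent": "LCX", "length": 28, "d_prox": 1.6, "d_dist": 1.2 }
  ],
  "stenoses": [
    { "segment": "LAD", "start": 12, "length": 8, "severity": 0.55, "ref_diameter": 3.0 }
  ],
  "metadata": { "name": "demo left coronary tree" }
}
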