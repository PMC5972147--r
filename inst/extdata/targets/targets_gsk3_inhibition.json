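{
  "schema_version": 1,
  "targets": [
    {
      "species": "SNAIL1_prot",
      "time_h": 24,
      "context": "gsk_i",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.5,
      "tol": 0.2,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "GLI1_nuc",
      "time_h": 24,
      "context": "gsk_i",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1,
      "tol": 0.15,
      "weight": 2,
      "cmp": "eq"
    }
  ]
}
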