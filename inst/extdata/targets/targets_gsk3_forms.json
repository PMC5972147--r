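{
  "schema_version": 1,
  "targets": [
    {
      "species": "GSK3_AA",
      "time_h": 8,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.3,
      "tol": 0.08,
      "weight": 2,
      "cmp": "eq"
    },
    {
      "species": "GSK3_AA",
      "time_h": 12,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1,
      "tol": 0.08,
      "weight": 1,
      "cmp": "eq"
    },
    {
      "species": "GSK3_D",
      "time_h": 12,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.75675675675676,
      "tol": 0.1,
      "weight": 2,
      "cmp": "eq"
    }
  ]
}
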