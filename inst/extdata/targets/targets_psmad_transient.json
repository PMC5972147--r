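{
  "schema_version": 1,
  "targets": [
    {
      "species": "pSMAD_nuc",
      "time_h": 8,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 3,
      "tol": 0.3,
      "weight": 1,
      "cmp": "eq"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 12,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 3.5,
      "tol": 0.2,
      "weight": 2,
      "cmp": "eq"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 24,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 2.2,
      "tol": 0.3,
      "weight": 1,
      "cmp": "eq"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 48,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.8,
      "tol": 0.3,
      "weight": 1,
      "cmp": "eq"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 72,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.8,
      "tol": 0.35,
      "weight": 1,
      "cmp": "eq"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 12,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 8,
      "target": 1.1,
      "tol": 0.07,
      "weight": 3,
      "cmp": "ge"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 12,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 24,
      "target": 1.4,
      "tol": 0.2,
      "weight": 2,
      "cmp": "ge"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 36,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 24,
      "target": 1,
      "tol": 0.08,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 48,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 36,
      "target": 1,
      "tol": 0.1,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 72,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 48,
      "target": 1.05,
      "tol": 0.08,
      "weight": 1,
      "cmp": "le"
    }
  ]
}
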