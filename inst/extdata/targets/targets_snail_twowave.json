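{
  "schema_version": 1,
  "targets": [
    {
      "species": "SNAIL1_mRNA",
      "time_h": 14,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 2.5,
      "tol": 0.25,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 24,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 14,
      "target": 0.8,
      "tol": 0.2,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 48,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 24,
      "target": 1.5,
      "tol": 0.15,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 6,
      "tol": 0.25,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 14,
      "target": 1.2,
      "tol": 0.2,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 16,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 2,
      "tol": 0.25,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 26,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 16,
      "target": 0.85,
      "tol": 0.15,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 72,
      "context": "const",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 3,
      "tol": 0.3,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 72,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 26,
      "target": 1.4,
      "tol": 0.25,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 72,
      "context": "const",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 16,
      "target": 1.5,
      "tol": 0.3,
      "weight": 1,
      "cmp": "ge"
    }
  ]
}
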