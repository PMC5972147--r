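{
  "schema_version": 1,
  "targets": [
    {
      "species": "pSMAD_nuc",
      "time_h": 12,
      "context": "pulse2",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 3.5,
      "tol": 0.14,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 48,
      "context": "pulse2",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.3,
      "tol": 0.15,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 12,
      "context": "pulse2",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.8,
      "tol": 0.16,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 48,
      "context": "pulse2",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.3,
      "tol": 0.1,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "pulse2",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.5,
      "tol": 0.2,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "GLI1_nuc",
      "time_h": 12,
      "context": "pulse2",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.25,
      "tol": 0.12,
      "weight": 1,
      "cmp": "le"
    },
    {
      "species": "GLI1_nuc",
      "time_h": 48,
      "context": "pulse2",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.25,
      "tol": 0.12,
      "weight": 2,
      "cmp": "le"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 12,
      "context": "pulse8",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 3.5,
      "tol": 0.14,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "pSMAD_nuc",
      "time_h": 48,
      "context": "pulse8",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 2.2,
      "tol": 0.3,
      "weight": 1,
      "cmp": "eq"
    },
    {
      "species": "GLI1_nuc",
      "time_h": 12,
      "context": "pulse8",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.25,
      "tol": 0.12,
      "weight": 3,
      "cmp": "le"
    },
    {
      "species": "GLI1_nuc",
      "time_h": 48,
      "context": "pulse8",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 2,
      "tol": 0.25,
      "weight": 2,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 12,
      "context": "pulse8",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 1.8,
      "tol": 0.16,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_prot",
      "time_h": 48,
      "context": "pulse8",
      "type": "fold",
      "ref_context": null,
      "ref_time_h": null,
      "target": 2,
      "tol": 0.25,
      "weight": 1,
      "cmp": "ge"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "pulse8",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 72,
      "target": 0.6,
      "tol": 0.3,
      "weight": 2,
      "cmp": "ge"
    }
  ]
}
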