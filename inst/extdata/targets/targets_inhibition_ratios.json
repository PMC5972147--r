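{
  "schema_version": 1,
  "targets": [
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "smad_i_early",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 72,
      "target": 0.09,
      "tol": 0.4,
      "weight": 2,
      "cmp": "eq"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "smad_i_late",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 72,
      "target": 0.7,
      "tol": 0.15,
      "weight": 4,
      "cmp": "eq"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "gli_i_early",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 72,
      "target": 0.07,
      "tol": 0.5,
      "weight": 3,
      "cmp": "eq"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 72,
      "context": "gli_i_late",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 72,
      "target": 0.25,
      "tol": 0.35,
      "weight": 4,
      "cmp": "eq"
    },
    {
      "species": "SNAIL1_mRNA",
      "time_h": 48,
      "context": "gli_i_early",
      "type": "ratio",
      "ref_context": "const",
      "ref_time_h": 48,
      "target": 0.12,
      "tol": 0.6,
      "weight": 0.5,
      "cmp": "eq"
    }
  ]
}
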