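{
  "sim": {
    "n_founders_per_line": 60,
    "n_snps": 600,
    "n_qtl": 100,
    "n_generations_pb": 3,
    "n_cb_sires": 30,
    "n_f1_sows": 60,
    "offspring_per_sire": 10,
    "line_context_sd": 1.1
  },
  "learner": {
    "epsilon": 0.1
  },
  "scenarios": [
    {
      "training": "trn1",
      "testing": "tst1",
      "learner": "svr",
      "subset_sizes": [50, 250]
    },
    {
      "training": "trn1",
      "testing": "tst2",
      "learner": "gblup"
    },
    {
      "training": "trn3",
      "testing": "tst2",
      "learner": "gblup"
    }
  ],
  "traits": ["rfi", "adg"],
  "seed": 1
}
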