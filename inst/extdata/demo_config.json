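{
  "cohort": {
    "n_patients": 6,
    "samples_per_patient": 2,
    "n_true_variants": 300,
    "n_artifact_variants": 200,
    "n_normals": 15,
    "n_catalog_mutations": 5000
  },
  "k_clusters": 2
}
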