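{
  "n_patients": 260,
  "patients_with_any_cna": 244,
  "patients_with_subchromosomal_cna": 208,
  "n_high_hyperdiploid": 82,
  "total_cnas": 1398
}
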