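{
  "name": "synthetic_phenol_demo",
  "descriptor_names": ["q_HO4", "q_O4", "q_C4"],
  "coefficients": [-30.0, 12.0, -8.0],
  "intercept": 18.5,
  "provenance": "Synthetic demonstration model for phenolic pKa from EEM charge descriptors (phenolic H, phenolic O, ipso C). Coefficients are illustrative only; substitute a published, QM-calibrated model for real predictions."
}
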