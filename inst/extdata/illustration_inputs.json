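{
  "comment": "Published inputs for the genotype-guided-prescribing illustration: per-year risk differences from the triangulated GMTE, carrier patient-years, and GP-diagnosed muscle-symptom case counts, plus the SAMS composition counts.",
  "star15": {
    "risk_diff_per_year": 0.0008,
    "carrier_patient_years": 80685,
    "cases_total": 1457,
    "cases_carriers": 369
  },
  "star20": {
    "risk_diff_per_year": 0.0005,
    "carrier_patient_years": 34076,
    "cases_total": 572,
    "cases_carriers": 165
  },
  "sams_composition": {
    "n_sams_total": 2131,
    "n_sams_star20_homozygotes": 211
  }
}
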