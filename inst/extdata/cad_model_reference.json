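{
  "description": "Published reference coefficient set for the final CAD phenotype algorithm, on the standardized-feature scale. Used as a scoring fixture; the standardization is the identity.",
  "feature_set": "structured_plus_nlp",
  "intercept": -10.19,
  "coefficients": {
    "nlp_cad": 1.44,
    "icd9_normalized": 0.4,
    "icd9_ihd": 0.35,
    "nlp_cad_procedure": 0.33,
    "followup_months": 0.22,
    "icd9_cad": 0.22,
    "cabg_pci": 0.2,
    "no_ldl": 0.1,
    "age": 0.1,
    "mean_ldl": -0.01,
    "nlp_never_smoker": -0.01,
    "nlp_current_smoker": -0.07,
    "echocardiogram": -0.16,
    "htn": -0.19,
    "icd9_total": -0.63
  },
  "provenance": {
    "nlp_cad": "nlp",
    "icd9_normalized": "structured",
    "icd9_ihd": "structured",
    "nlp_cad_procedure": "nlp",
    "followup_months": "structured",
    "icd9_cad": "structured",
    "cabg_pci": "structured",
    "no_ldl": "structured",
    "age": "structured",
    "mean_ldl": "structured",
    "nlp_never_smoker": "nlp",
    "nlp_current_smoker": "nlp",
    "echocardiogram": "structured",
    "htn": "structured",
    "icd9_total": "structured"
  }
}
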