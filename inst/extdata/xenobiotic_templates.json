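{
  "_comment": "Cofactor-only reaction templates for splicing xenobiotic metabolism into a metabolic network. The drug species themselves never appear: they are balanced by the pharmacokinetic driver, so only the endogenous cofactor demand is represented. 'cofactors' maps a role name to a signed stoichiometric coefficient; 'options' are opt-in cofactor sets; 'locations' lists allowed compartment names (null = unrestricted, used for membrane transport templates).",
  "oxidation": {
    "phase": "I",
    "cofactors": {"o2": -1},
    "options": {"nadph": {"nadph": -1, "nadp": 1}},
    "locations": ["cytosol", "mitochondria", "peroxisome"]
  },
  "hydrolysis": {
    "phase": "I",
    "cofactors": {"h2o": -1},
    "locations": ["cytosol", "mitochondria", "peroxisome"]
  },
  "reduction": {
    "phase": "I",
    "cofactors": {"nadph": -1, "nadp": 1},
    "locations": ["cytosol", "mitochondria", "peroxisome"]
  },
  "gsh_conjugation": {
    "phase": "II",
    "cofactors": {"gsh": -1},
    "locations": ["cytosol"]
  },
  "sulfation": {
    "phase": "II",
    "cofactors": {"paps": -1, "pap": 1},
    "locations": ["cytosol"]
  },
  "acetylation": {
    "phase": "II",
    "cofactors": {"accoa": -1, "coa": 1},
    "locations": ["cytosol"]
  },
  "sugar_conjugation": {
    "phase": "II",
    "cofactors": {"udpsug": -1, "adp": 1},
    "locations": ["microsome", "endoplasmic_reticulum"]
  },
  "methylation": {
    "phase": "II",
    "cofactors": {"sam": -1, "sah": 1},
    "locations": ["mitochondria", "nucleus"]
  },
  "aa_conjugation": {
    "phase": "II",
    "cofactors": {"aa": -1},
    "locations": ["mitochondria"]
  },
  "metabolic_integration": {
    "phase": "III",
    "cofactors": {"product": 1},
    "options": {"consumes": {"substrate": -1}},
    "locations": ["cytosol", "mitochondria", "peroxisome", "nucleus", "lysosome", "endoplasmic_reticulum"]
  },
  "atp_transporter": {
    "phase": "III",
    "cofactors": {"atp": -1, "adp": 1, "pi": 1},
    "locations": null
  },
  "sym_antiporter": {
    "phase": "III",
    "cofactors": {"ion_out": -1, "ion_in": 1},
    "locations": null
  }
}
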