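{
  "genes": {
    "MYBPC3": {"tier": "tier1", "associations": [{"disease": "HCM", "validity": "definitive"}]},
    "MYH7":   {"tier": "tier1", "associations": [{"disease": "HCM", "validity": "definitive"},
                                                  {"disease": "LVNC", "validity": "definitive"},
                                                  {"disease": "DCM", "validity": "moderate"}]},
    "TNNT2":  {"tier": "tier1", "associations": [{"disease": "HCM", "validity": "definitive"},
                                                  {"disease": "DCM", "validity": "moderate"}]},
    "TNNI3":  {"tier": "tier1", "associations": [{"disease": "HCM", "validity": "definitive"},
                                                  {"disease": "RCM", "validity": "definitive"}]},
    "PRKAG2": {"tier": "tier1", "associations": [{"disease": "HCM", "validity": "definitive"}]},
    "TTN":    {"tier": "tier1", "associations": [{"disease": "DCM", "validity": "definitive"}]},
    "FLNC":   {"tier": "tier1", "associations": [{"disease": "DCM", "validity": "definitive"},
                                                  {"disease": "ACM", "validity": "moderate"}]},
    "LMNA":   {"tier": "tier1", "associations": [{"disease": "DCM", "validity": "definitive"}]},
    "KCNQ1":  {"tier": "tier1", "associations": [{"disease": "LQTS", "validity": "definitive"}]},
    "KCNH2":  {"tier": "tier1", "associations": [{"disease": "LQTS", "validity": "definitive"}]},
    "SCN5A":  {"tier": "tier1", "associations": [{"disease": "BrS", "validity": "definitive"},
                                                  {"disease": "LQTS", "validity": "definitive"},
                                                  {"disease": "SSS", "validity": "definitive"}]},
    "RYR2":   {"tier": "tier1", "associations": [{"disease": "CPVT", "validity": "definitive"}]},
    "PKP2":   {"tier": "tier1", "associations": [{"disease": "ACM", "validity": "definitive"}]},
    "DSP":    {"tier": "tier1", "associations": [{"disease": "ACM", "validity": "definitive"},
                                                  {"disease": "DCM", "validity": "moderate"}]},
    "PTPN11": {"tier": "tier1", "associations": [{"disease": "NoonanLVH", "validity": "definitive"}]},
    "MYL2":   {"tier": "tier1", "associations": [{"disease": "HCM", "validity": "definitive"}]},
    "FHOD3":  {"tier": "tier2", "associations": [{"disease": "HCM", "validity": "moderate"}]},
    "ACTN2":  {"tier": "tier2", "associations": [{"disease": "HCM", "validity": "moderate"},
                                                  {"disease": "DCM", "validity": "moderate"}]},
    "FHL1":   {"tier": "tier2", "associations": [{"disease": "HCM", "validity": "moderate"}]},
    "ALPK3":  {"tier": "tier2", "associations": [{"disease": "HCM", "validity": "moderate"}]},
    "TBX5":   {"tier": "tier2", "associations": [{"disease": "LVNC", "validity": "moderate"}]}
  },
  "max_credible_popmax_af": {
    "HCM": 4e-05,
    "DCM": 1e-05,
    "LVNC": 1e-05,
    "ACM": 1e-05,
    "BrS": 1e-05,
    "LQTS": 1e-05,
    "CPVT": 1e-05,
    "RCM": 1e-05,
    "NoonanLVH": 1e-05,
    "SSS": 1e-05
  }
}
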