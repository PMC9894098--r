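{
  "description": "Channel catalog for composable custom therapeutic cells. Baseline values are conductance densities (nS/pF) referenced to the fixed 40 pF custom-cell capacitance, except: cf_nak is a maximal current density (pA/pF) and cm_cal is a permeability (cm/s, GHK formulation). Scaling factors in a custom-cell spec multiply these baselines. Source-model leakage/background currents are excluded by design.",
  "version": "1.0",
  "capacitance_pf": 40.0,
  "fixed_concentrations_mM": {"nai": 10.0, "ki": 140.0, "cai": 1.0e-4},
  "passive_reversal_mv": -20.0,
  "channels": [
    {"name": "cic_na",       "source": "hCIC",    "baseline": 0.075,  "unit": "nS/pF", "description": "hCIC fast sodium current", "reconstructed": true},
    {"name": "cic_kir",      "source": "hCIC",    "baseline": 0.015,  "unit": "nS/pF", "description": "hCIC inward rectifying K+ current", "reconstructed": true},
    {"name": "cic_kca",      "source": "hCIC",    "baseline": 0.05,   "unit": "nS/pF", "description": "hCIC large-conductance Ca2+-activated K+ current (BK)", "reconstructed": true},
    {"name": "cic_to",       "source": "hCIC",    "baseline": 0.04,   "unit": "nS/pF", "description": "hCIC transient outward K+ current", "reconstructed": true},
    {"name": "msc_to",       "source": "hMSC",    "baseline": 0.035,  "unit": "nS/pF", "description": "hMSC transient outward K+ current, time-dependent component", "reconstructed": true},
    {"name": "msc_to_ss",    "source": "hMSC",    "baseline": 0.01,   "unit": "nS/pF", "description": "hMSC transient outward K+ current, steady-state component", "reconstructed": true},
    {"name": "msc_na",       "source": "hMSC",    "baseline": 0.025,  "unit": "nS/pF", "description": "hMSC TTX-sensitive sodium current", "reconstructed": true},
    {"name": "msc_cal",      "source": "hMSC",    "baseline": 0.012,  "unit": "nS/pF", "description": "hMSC L-type calcium current", "reconstructed": true},
    {"name": "msc_kca",      "source": "hMSC",    "baseline": 0.03,   "unit": "nS/pF", "description": "hMSC Ca2+-activated K+ current", "reconstructed": true},
    {"name": "msc_dr",       "source": "hMSC",    "baseline": 0.05,   "unit": "nS/pF", "description": "hMSC delayed rectifier K+ current", "reconstructed": true},
    {"name": "cf_kv",        "source": "CF",      "baseline": 0.25,   "unit": "nS/pF", "description": "fibroblast time- and voltage-dependent K+ current (MacCannell)", "reconstructed": false},
    {"name": "cf_kir",       "source": "CF",      "baseline": 0.4822, "unit": "nS/pF", "description": "fibroblast inward rectifying K+ current (MacCannell)", "reconstructed": false},
    {"name": "cf_nak",       "source": "CF",      "baseline": 2.002,  "unit": "pA/pF", "description": "fibroblast Na+/K+ pump current (MacCannell)", "reconstructed": false},
    {"name": "cm_na",        "source": "hCM",     "baseline": 14.838, "unit": "nS/pF", "description": "cardiomyocyte fast sodium current (ten Tusscher-Panfilov formulation)", "reconstructed": false},
    {"name": "cm_nal",       "source": "hCM",     "baseline": 0.0075, "unit": "nS/pF", "description": "cardiomyocyte late sodium current", "reconstructed": false},
    {"name": "cm_to",        "source": "hCM",     "baseline": 0.02,   "unit": "nS/pF", "description": "cardiomyocyte transient outward K+ current", "reconstructed": false},
    {"name": "cm_cal",       "source": "hCM",     "baseline": 1.0e-4, "unit": "cm/s",  "description": "cardiomyocyte L-type Ca2+ channel permeability (GHK)", "reconstructed": false},
    {"name": "cm_kr",        "source": "hCM",     "baseline": 0.046,  "unit": "nS/pF", "description": "cardiomyocyte rapid delayed rectifier K+ current", "reconstructed": false},
    {"name": "cm_ks",        "source": "hCM",     "baseline": 0.0034, "unit": "nS/pF", "description": "cardiomyocyte slow delayed rectifier K+ current", "reconstructed": false},
    {"name": "cm_k1",        "source": "hCM",     "baseline": 0.1908, "unit": "nS/pF", "description": "cardiomyocyte inward rectifier K+ current", "reconstructed": false},
    {"name": "passive_leak", "source": "passive", "baseline": 0.025,  "unit": "nS/pF", "description": "linear leak of the purely passive cell (reversal -20 mV); config-exposed stand-in, not a physiologic channel", "reconstructed": true}
  ]
}
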