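{
  "description": "Multiplicative remodeling of the endocardial ventricular cardiomyocyte model representing heart failure with reduced ejection fraction. Applied on top of the healthy baseline conductances/permeabilities and fluxes.",
  "units": "dimensionless multipliers",
  "version": "1.0",
  "factors": {
    "g_nal": 1.8,
    "tau_hl": 1.8,
    "g_to": 0.4,
    "g_k1": 0.68,
    "g_ncx": 1.75,
    "p_nak": 0.7,
    "j_up": 0.55,
    "j_leak": 1.3,
    "camk": 1.5
  },
  "notes": {
    "g_nal": "late Na+ conductance increased 80%",
    "tau_hl": "late Na+ inactivation slowed 80%",
    "g_to": "transient outward K+ conductance reduced 60%",
    "g_k1": "inward rectifier K+ conductance reduced 32%",
    "g_ncx": "Na+/Ca2+ exchanger activity increased 75%",
    "p_nak": "Na+/K+ pump activity reduced 30%",
    "j_up": "SERCA uptake reduced 45%",
    "j_leak": "SR leak increased 30%",
    "camk": "CaMKII activity increased 50%"
  }
}
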