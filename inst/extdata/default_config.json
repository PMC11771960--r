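{
  "units": {
    "burster_F": {
      "C": 20,
      "gL": 2.8,
      "EL": -68,
      "gNaP": 6,
      "ENa": 50,
      "theta_m": -40,
      "sigma_m": 6,
      "theta_h": -45,
      "sigma_h": 8,
      "tau0": 600
    },
    "burster_E": {
      "C": 20,
      "gL": 2.8,
      "EL": -50,
      "gNaP": 6,
      "ENa": 50,
      "theta_m": -40,
      "sigma_m": 6,
      "theta_h": -45,
      "sigma_h": 8,
      "tau0": 300
    },
    "simple": {
      "C": 20,
      "gL": 1,
      "EL": -52
    }
  },
  "weights": {
    "F_InF": 2,
    "InF_E": 1.69,
    "E_InE": 2,
    "InE_F": 0.61,
    "F_V0D": 2,
    "V0D_F": 7,
    "F_V2a": 2,
    "V2a_V0V": 2,
    "V0V_Ini": 2,
    "Ini_F": 1,
    "F_V3": 1.5,
    "V3_F": 0.15,
    "E_V3E": 0.5,
    "V3E_E": 0.15,
    "a_F": 0.35,
    "a_Fc": 0.14,
    "a_V2a": 0.1,
    "a_V0V": 0.2,
    "g_E": 1,
    "E1_F": 1.6,
    "E1_Ini": 0.374,
    "E2_E": 1.11,
    "E2_V3E": 0.5
  },
  "globals": {
    "k_PSI": 2,
    "k_E1": 1,
    "k_E2": 1,
    "T_ramp": 1,
    "tau_reset": 0.52,
    "E_SynE": -10,
    "E_SynI": -75,
    "V_thr": -50,
    "V_max": 0,
    "gamma": 0.5
  }
}
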