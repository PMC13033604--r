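{
  "parameters": {
    "lg_tumor": 0.2,
    "Vi_tumor0": 25,
    "a_c": 0.25,
    "b_c": 0.025,
    "a_IM": 0.4,
    "b_IM": 0.05,
    "Clear_c_dead": 0.25,
    "Ac_DC": 4e-11,
    "Ac_M1": 4e-12,
    "Ac_dead_DC": 8e-11,
    "Ac_dead_M1": 8e-12,
    "k_prol_TN": 2,
    "k_TN": {
      "control": 9e-10,
      "rt": 9e-09
    },
    "k_rc1": {
      "control": 2e-07,
      "rt": 6e-06
    },
    "TN0": 1000000,
    "N_exp": 9000,
    "s_Treg": 2e-07,
    "s_M2": 1e-07,
    "v_cell": 1e-06,
    "phi_int": 0.5,
    "phi_vas": 0.07,
    "death": {
      "DC": 0.3,
      "M1": 0.3,
      "M2": 0.3,
      "TREG": 0.2,
      "TE1": 0.25,
      "APC": 0.7
    },
    "baseline_total": {
      "DC": 2000000,
      "M1": 5000000,
      "M2": 5000000,
      "TREG": 3000000,
      "TE1": 200000,
      "APC": 0
    }
  },
  "metadata": {
    "units": {
      "rates": "1/day",
      "volumes": "mm3",
      "interaction_constants": "per (cells/mL) per day",
      "radiosensitivity": "1/Gy and 1/Gy2",
      "suppression": "mL/cell",
      "v_cell": "mm3/cell"
    }
  }
}
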