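{
  "neuron":  { "C_m": 250, "g_L": 16.667, "E_L": -70, "V_th": -60, "t_ref": 3 },
  "synapse": {
    "J":     { "ee": 0.26, "ei": 0.2, "ie": 0.4, "ii": 0.33, "ex": 0.5, "ix": 0.5 },
    "tau":   { "ee": 3, "ei": 3, "ie": 5, "ii": 5, "ex": 3, "ix": 5 },
    "delay": { "ee": 1.5, "ei": 1.5, "ie": 1.5, "ii": 1.5, "ex": 1, "ix": 1 },
    "E_rev_exc": 0, "E_rev_inh": -80, "J_retinal": 1.1
  },
  "network": {
    "grid_side": 80, "sigma_E": 16, "sigma_I": 20,
    "p": { "ee": 0.135, "ei": 0.135, "ie": 0.135, "ii": 0.135 }
  },
  "protocol": { "condition": "center_after_surround", "n_trials": 20,
                "surround_rate": 300 },
  "analysis": { "threshold": 0.2, "reversal_e": -10, "reversal_i": -75,
                "junction": -10, "delta_t": 20 },
  "seeds":    { "master": 1 }
}
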