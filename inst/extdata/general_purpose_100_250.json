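{
  "name": "general_purpose_100_250",
  "geometry": {
    "d_iso_cm": 230.0,
    "iso_depth_cm": 22.0,
    "environment": "in_water"
  },
  "calibration": {
    "alpha_E": 8.0e-9,
    "p_E": 4.1,
    "hd_ref_iso_Sv_per_Gy": 1.2e-4,
    "ref_energy_MeV": 100.0
  },
  "apportionment": {
    "type": "energy_dependent",
    "a1": -4.8e-4,
    "b1": 0.6,
    "a2": 0.12,
    "b2": 130.0,
    "c2": 5.0,
    "d2": -1.3e-11,
    "a3": 0.4,
    "a4": 1.2e-7,
    "b4": -6.6e-5,
    "c4": 0.011,
    "renormalize": true,
    "energy_range_MeV": [100.0, 250.0]
  },
  "transport": {
    "alpha_cm_inv": [0.013, 0.013, 0.032, 0.33],
    "sigma_cm": [14.0, 77.0, 3900.0, 3900.0],
    "q": 1.13
  }
}
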