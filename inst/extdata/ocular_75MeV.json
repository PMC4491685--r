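{
  "name": "ocular_75MeV",
  "geometry": {
    "d_iso_cm": 100.0,
    "iso_depth_cm": 0.0,
    "environment": "in_air"
  },
  "hd_iso_Sv_per_Gy": 5.2e-5,
  "energy_MeV": 75.0,
  "apportionment": {
    "type": "scalar",
    "C1": 0.011,
    "C2": 0.78,
    "C3": 0.10,
    "C4": 0.096,
    "renormalize": true
  },
  "transport": {
    "alpha_cm_inv": [0.0, 0.0, 0.0, 0.0],
    "sigma_cm": [9.4, 1000.0, 4200.0, 4200.0],
    "q": 1.5
  }
}
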