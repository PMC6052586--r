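{
  "akreos_ao": {
    "name": "Akreos AO",
    "interval": 0.5,
    "tolerance_sd": 0.4,
    "a_constant": 118.24,
    "haigis_a0": 1.706,
    "haigis_a1": 0.279,
    "haigis_a2": 0.087,
    "power_min": 15.5,
    "power_max": 25
  },
  "softec_hd": {
    "name": "Softec HD",
    "interval": 0.25,
    "tolerance_sd": 0.11,
    "a_constant": 118.17,
    "haigis_a0": 0.565,
    "haigis_a1": 0.24,
    "haigis_a2": 0.138,
    "power_min": 15.5,
    "power_max": 25
  }
}
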