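{
  "name": "karplus_schulz",
  "provenance": "Karplus PA, Schulz GE (1985) Prediction of chain flexibility in proteins. Naturwissenschaften 72:212-213. Flexibility parameter for no rigid neighbors (AAindex KARP850101), a normalized B-factor-derived scale.",
  "values": {
    "A": 1.041, "C": 0.960, "D": 1.033, "E": 1.094, "F": 0.930,
    "G": 1.142, "H": 0.982, "I": 1.002, "K": 1.093, "L": 0.967,
    "M": 0.947, "N": 1.117, "P": 1.055, "Q": 1.165, "R": 1.038,
    "S": 1.169, "T": 1.073, "V": 0.982, "W": 0.925, "Y": 0.961
  }
}
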