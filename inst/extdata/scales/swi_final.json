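{
  "name": "swi_final",
  "provenance": "Final SWI residue weights: mean of per-fold Nelder-Mead-optimized weight vectors from 10-fold homology-aware cross-validation on the PSI:Biology expression outcomes, initialized from Smith et al. 2003 normalized B-factors. Transcribed from the method's published reference implementation.",
  "values": {
    "A": 0.8356471476582918,
    "C": 0.5208088354857734,
    "D": 0.9079044671339564,
    "E": 0.9876987431418378,
    "F": 0.5849790194237692,
    "G": 0.7997168496420723,
    "H": 0.8947913996466419,
    "I": 0.6784124413866582,
    "K": 0.9267104557513497,
    "L": 0.6554221515081433,
    "M": 0.6296623675420369,
    "N": 0.8597433107431216,
    "P": 0.8095327205898300,
    "Q": 0.7914735842896397,
    "R": 0.7712466317693457,
    "S": 0.7440908318492778,
    "T": 0.8096922697856334,
    "V": 0.7357186674275689,
    "W": 0.6903146047744241,
    "Y": 0.6112801822947587
  }
}
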