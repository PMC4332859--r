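{
  "description": "Unified oligonucleotide nearest-neighbor parameters for DNA duplex formation at 1 M NaCl. dH in kcal/mol, dS in cal/(mol K). Stacks are written 5'->3' on the top strand; the 6 stacks not listed are looked up via their reverse complement.",
  "stacks": {
    "AA": [-7.9, -22.2],
    "AT": [-7.2, -20.4],
    "TA": [-7.2, -21.3],
    "CA": [-8.5, -22.7],
    "GT": [-8.4, -22.4],
    "CT": [-7.8, -21.0],
    "GA": [-8.2, -22.2],
    "CG": [-10.6, -27.2],
    "GC": [-9.8, -24.4],
    "GG": [-8.0, -19.9]
  },
  "initiation": {
    "GC": [0.1, -2.8],
    "AT": [2.3, 4.1]
  }
}
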