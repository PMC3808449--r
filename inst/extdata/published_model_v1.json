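{
  "format": "immunopep-model",
  "format_version": 1,
  "log_enrichment": {
    "A": 0.127,
    "C": -0.175,
    "D": 0.072,
    "E": 0.325,
    "F": 0.38,
    "G": 0.11,
    "H": 0.105,
    "I": 0.432,
    "K": -0.7,
    "L": -0.036,
    "M": -0.57,
    "N": -0.021,
    "P": -0.036,
    "Q": -0.376,
    "R": 0.168,
    "S": -0.537,
    "T": 0.126,
    "V": 0.134,
    "W": 0.719,
    "Y": -0.012
  },
  "importance": [0, 0, 0.1, 0.31, 0.3, 0.29, 0.26, 0.18, 0],
  "masks": {
    "HLA-B*08:01": [2, 5, 9]
  },
  "default_rule": ["1", "2", "last"],
  "metadata": {
    "name": "published final model",
    "provenance": "Log-enrichment scores transcribed by the package authors from the published immunogenicity model's score table (the table distributed with the public web tool); importance weights and the HLA-B*08:01 anchor set transcribed from the published per-position divergence table and results text.",
    "note": "Importance weights are the per-position Kullback-Leibler divergences; positions 1, 2 and 9 are anchors under the default rule and carry weight 0."
  }
}
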