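[
  {
    "reduced": [],
    "oxidized": []
  },
  {
    "reduced": ["N"],
    "oxidized": ["N1", "N2"]
  },
  {
    "reduced": ["O"],
    "oxidized": ["O1", "O2"]
  },
  {
    "reduced": ["N", "O"],
    "oxidized": ["N1", "N2", "O1", "O2"]
  }
]
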