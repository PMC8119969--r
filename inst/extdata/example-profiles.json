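{
  "moral":   {"C": 0.40, "P_Moral": 0.65, "P_Hypocritical": 0.35, "P_Antisocial": 0.20, "b": 0.10},
  "neutral": {"C": 0.40, "P_Moral": 0.40, "P_Hypocritical": 0.25, "P_Antisocial": 0.20, "b": 0.10}
}
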