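{
  "seabuckthorn": {
    "capric acid": ["rspo4", "pcsk1"],
    "caproic acid": ["plg", "casr"],
    "caprylic acid": ["acacb"],
    "gallic acid": ["jun", "mapk3", "p53", "mapk1"],
    "malic acid": ["acacb"]
  }
}
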