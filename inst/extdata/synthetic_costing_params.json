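{
  "reference_year": 2010,
  "reference_wage": 3549,
  "cpi_table": {
    "Alpha": {"2006": 85.0, "2010": 100.0},
    "Beta": {"2004": 70.0, "2010": 100.0}
  },
  "local_wage_table": {
    "Alpha": {"2010": 1200.0},
    "Beta": {"2010": 5200.0}
  }
}
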