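{
  "exposed": {
    "doomed": "4/15",
    "causal": "1/3",
    "preventive": "1/15",
    "immune": "1/3"
  },
  "unexposed": {
    "doomed": "1/3",
    "causal": "0",
    "preventive": "4/15",
    "immune": "2/5"
  },
  "prevalence": "3/5"
}
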