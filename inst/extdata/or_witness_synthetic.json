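{
  "exposed": {
    "doomed": "1/2",
    "causal": "0",
    "preventive": "1/6",
    "immune": "1/3"
  },
  "unexposed": {
    "doomed": "1/3",
    "causal": "7/15",
    "preventive": "0",
    "immune": "1/5"
  },
  "prevalence": "1/2"
}
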