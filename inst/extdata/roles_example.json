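{
  "skin": 1,
  "liver": 2,
  "tumor": 3,
  "vessel": [4],
  "bone": [5],
  "lung": []
}
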