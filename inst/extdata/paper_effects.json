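{
  "description": "Reference MODEL-vs-WT effect table: pooled DA b-wave reduction 130.49 uV; DA OP delay 0.7925 ms per wavelet (3.17 ms on the summed four-peak timing measure); DA a-wave delay 1.01 ms at low luminances only; uniform LA PhNR reduction 6.79 uV; null effects elsewhere.",
  "effects": [
    {"component": "b",    "adaptation": "DA", "amplitude_shift": 130.49},
    {"component": "op",   "adaptation": "DA", "latency_shift": 0.7925},
    {"component": "a",    "adaptation": "DA", "latency_shift": 1.01, "lum_max": 0.3},
    {"component": "phnr", "adaptation": "LA", "amplitude_shift": 6.79}
  ]
}
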