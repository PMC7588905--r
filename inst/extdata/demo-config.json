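{
  "resolution": [320, 240],
  "noise_sd": 2,
  "seed": 42,
  "ramp": 3,
  "schedule": [
    {"start": 0,    "end": 300,  "activity": "stand"},
    {"start": 300,  "end": 600,  "activity": "walk", "speed": 8},
    {"start": 600,  "end": 900,  "activity": "sit"},
    {"start": 900,  "end": 1200, "activity": "hand_activity"},
    {"start": 1200, "end": 1500, "activity": "absent"},
    {"start": 1500, "end": 1800, "activity": "visitor", "base": "sit"}
  ]
}
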