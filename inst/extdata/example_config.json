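{
  "scenario": {
    "ih": "hay",
    "hot_zone": true,
    "max_seg_len": 20
  },
  "sim": {
    "dt": 0.025,
    "t_stop": 120,
    "settle": 400,
    "seed": 1
  },
  "protocol": {
    "distances": [
      200,
      400,
      600,
      800,
      1000
    ],
    "kind": "pulse",
    "duration": 2,
    "tol": 0.01
  }
}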