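{
  "seed": 1,
  "scenario": {
    "n_regions": 16,
    "driver": 1,
    "n_targets": 5,
    "coupling_strength": 0.35,
    "delta_gain": 8,
    "duration": 60,
    "rate": 256,
    "sensor_snr": 5
  },
  "preprocess": {
    "bandpass": [0.5, 80],
    "notch": [48, 52],
    "epoch_seconds": 2
  },
  "inverse": { "alpha": "auto", "snr": 3, "avg_ref": true },
  "psd": { "window_s": 2, "overlap": 0.5 },
  "network": {
    "order": "auto",
    "max_order": 6,
    "ridge": 0.001,
    "densities": [0.05, 0.5, 0.05],
    "hub_cutoff": 0.95,
    "bands": ["delta"]
  },
  "si": {
    "band": "delta",
    "realizations": 200,
    "t_max": 100,
    "dt": 0.01,
    "coupling_gain": 0.5,
    "d0": 0.1,
    "threshold": 0.5,
    "cutoff": 0.95
  }
}
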