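{
  "seed": 42,
  "out_dir": "fiberpnn_run",
  "photometry": {
    "duration_s": 120,
    "frame_rate_hz": 40,
    "event_rate_hz": 0.1,
    "event_amplitude_dff": 0.05,
    "artifact_rate_hz": 0.05,
    "artifact_amplitude": 10,
    "noise_sd": 1
  },
  "homecage": { "duration_s": 300, "event_rate_hz": 0.05 },
  "behavior": { "mean_bout_s": 8, "sample_rate_hz": 10 },
  "dff": { "reference": "isosbestic", "hc_window": [60, 240] },
  "epochs": { "min_bout_s": 2 },
  "metrics": { "min_peak_gap_s": 1 },
  "effects": {
    "n1": 14, "n2": 14, "true_d": 0.8,
    "n_resamples": 1000, "ci_level": 0.95, "method": "BCa"
  }
}
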