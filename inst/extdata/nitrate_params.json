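{
  "sensor": "synthetic nitrate-N (mg N/L), 1-min cadence",
  "windows": [
    {
      "window_id": 1,
      "width": 961,
      "statistic": "mean",
      "topadd": 0.145,
      "bottomsub": 0.145,
      "std_factor": 0.6,
      "use_uncertainty": false
    },
    {
      "window_id": 2,
      "width": 961,
      "statistic": "mean",
      "topadd": 0.135,
      "bottomsub": 0.135,
      "std_factor": 0.6,
      "use_uncertainty": false
    },
    {
      "window_id": 3,
      "width": 49,
      "statistic": "median",
      "topadd": 0.06,
      "bottomsub": 0.06,
      "std_factor": 1.8,
      "use_uncertainty": false
    },
    {
      "window_id": 4,
      "width": 5,
      "statistic": "mean",
      "topadd": 0.12,
      "bottomsub": 0.12,
      "std_factor": 1,
      "use_uncertainty": false
    },
    {
      "window_id": 5,
      "width": 5,
      "statistic": "triangular_mean",
      "topadd": 0.1,
      "bottomsub": 0.1,
      "std_factor": 0.9,
      "use_uncertainty": false
    }
  ],
  "uncertainty": {
    "pct": 0,
    "constant": 0
  },
  "warmup_records": 300,
  "cooldown_records": 300,
  "min_valid_in_window": 3,
  "include_center": true
}
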