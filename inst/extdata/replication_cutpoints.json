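{
  "pafs_score": {"variable": "pafs_score", "threshold": 19, "direction": "ge"},
  "epds_score": {"variable": "epds_score", "threshold": 12.5, "direction": "ge"},
  "sleep_hours_avg": {"variable": "sleep_hours_avg", "threshold": 6.83, "direction": "le"},
  "weekly_mileage": {"variable": "weekly_mileage", "threshold": 15.25, "direction": "ge"},
  "weeks_to_first_run": {"variable": "weeks_to_first_run", "threshold": 24.5, "direction": "ge"}
}
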