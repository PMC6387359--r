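{
  "comment": "Per-sensor incremental currents (mA) reconstructed by solving the published per-configuration reduction cells (each cell = sum of disabled sensors' increments) with env_temp = humidity symmetry; i_total_mA pinned by the published percentage values. Wrist/ankle accelerometer increments are not identifiable from those cells and carry the bench-measured values; they only matter for the power-weighted penalty.",
  "sensors": {
    "body_temp": 0.312,
    "env_temp": 0.263,
    "humidity": 0.263,
    "eda": 0.312,
    "hr": 2.673,
    "wrist_accel": 0.32,
    "ankle_accel": 2.70
  },
  "i_total_mA": 9.9466
}
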