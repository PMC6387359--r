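{
  "comment": "Bench measurements of the prototype: wrist full 4.13 mA (no accel 3.81, no environmental 3.86), chest full 5.89 mA (no accel 3.19, no EKG 3.22). Increments: wrist accel 0.32, environmental pair 0.27 split evenly, chest accel 2.70, EKG 2.67. Ankle accelerometer uses the chest-accel increment; skin temperature and EDA use the wrist-accel increment. i_total = wrist + chest full function.",
  "sensors": {
    "body_temp": 0.32,
    "env_temp": 0.135,
    "humidity": 0.135,
    "eda": 0.32,
    "hr": 2.67,
    "wrist_accel": 0.32,
    "ankle_accel": 2.70
  },
  "i_total_mA": 10.02
}
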