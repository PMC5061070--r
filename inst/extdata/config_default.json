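{
  "plant": {
    "hand_mass": 0.45,
    "cog_offset": 0.06,
    "inertia_fe": 0.002,
    "inertia_rud": 0.002,
    "damping_fe": 0.005,
    "damping_rud": 0.005,
    "orientation": "downward",
    "gravity": 9.81,
    "cable_stiffness": 20000,
    "actuator_max_speed": 0.1,
    "loop_period": 0.005,
    "physics_dt": 0.001,
    "angle_noise_sd": 0.1,
    "force_noise_sd": 0.1,
    "joint_limits": {"fe": [-80, 80], "rud": [-40, 40]}
  },
  "controller": {
    "strategy": "hybrid",
    "f0": 10,
    "rho": 140,
    "ff_gain": 1,
    "hysteresis_band": 2,
    "switch_margin_mm": 0.3,
    "axis_gains": {
      "fe": {"kp": 0.0327, "ki": 0.862, "kd": 0.00062,
             "integral_limit": 50, "deriv_filter_tau": 0.02},
      "rud": {"kp": 0.0053, "ki": 0.140, "kd": 0.0001,
              "integral_limit": 50, "deriv_filter_tau": 0.02}
    },
    "torque_gains": {
      "fe": {"kp": 0.08, "ki": 0.8, "kd": 0.002,
             "integral_limit": 20, "deriv_filter_tau": 0.02},
      "rud": {"kp": 0.08, "ki": 0.8, "kd": 0.002,
              "integral_limit": 20, "deriv_filter_tau": 0.02}
    },
    "force_gains": {"kp": 6, "ki": 4, "integral_limit": 100}
  },
  "trajectory": {"motion": "FE30", "period": 4, "n_cycles": 3},
  "muscle_table": "muscles_default.csv",
  "seed": 1
}
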