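{
  "mouse_freq": {
    "low": {
      "center_hz": 450,
      "no_go_hz": [310, 345, 380, 415],
      "go_hz": [485, 520, 555, 590],
      "a_ref_um": 5.6,
      "probe_amps_um": [8.6, 7.1, 4.1, 2.6, 1.1],
      "n_mice": 4,
      "min_repeats": 10,
      "probe_fraction": 0.3
    },
    "middle": {
      "center_hz": 1000,
      "no_go_hz": [900, 925, 950, 975],
      "go_hz": [1025, 1050, 1075, 1100],
      "a_ref_um": 3.8,
      "probe_amps_um": [6.9, 5.4, 4.8, 2.7, 2.1, 1.8],
      "n_mice": 4,
      "min_repeats": 10,
      "probe_fraction": 0.3
    },
    "high": {
      "center_hz": 1600,
      "no_go_hz": [1500, 1525, 1550, 1575],
      "go_hz": [1625, 1650, 1675, 1700],
      "a_ref_um": 3.8,
      "probe_amps_um": [6.9, 5.4, 4.8, 2.7, 2.1, 1.8],
      "n_mice": 6,
      "min_repeats": 10,
      "probe_fraction": 0.3
    }
  },
  "human_freq": {
    "f_ref_hz": [160, 200, 280, 440, 480],
    "delta_max_hz": [64, 128, 128, 256, 256],
    "step_min_hz": [8, 8, 16, 32, 32],
    "step_max_hz": [16, 32, 32, 64, 64],
    "a_test_um": 11.8,
    "a_ref_um": [7.4, 8.4, 9.8, 11.8, 14.2, 16.5, 18.9],
    "min_trials_per_a_ref": 70,
    "n_subjects": 9
  },
  "human_amp": {
    "a_ref_um": [6, 8, 10, 12],
    "delta_max_up_um": [12, 10, 8, 6],
    "delta_max_down_um": [5, 7, 9, 11],
    "step_min_um": 1,
    "step_max_um": 3,
    "f_test_hz": 200,
    "f_ref_hz": [75, 100, 150, 200, 266, 400, 534],
    "n_subjects": 10
  },
  "mouse_detection": {
    "frequencies_hz": [200, 450, 700, 1000, 1300, 1600, 2000],
    "n_mice": 7,
    "n_sessions": 5,
    "step_db": 4,
    "bout_min_present": 6,
    "bout_min_total": 12,
    "alpha": 0.05
  },
  "human_detection": {
    "frequencies_hz": [10, 25, 50, 75, 100, 200, 300, 400, 500, 600, 700, 800, 900, 1000],
    "n_subjects": 19,
    "start_step_db": 12,
    "step_db_min": 3,
    "reversal_limit": 5
  }
}
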