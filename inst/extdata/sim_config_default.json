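{
  "n_subjects": 10,
  "n_channels": 32,
  "sampling_rate": 250,
  "epoch": [-200, 700],
  "analysis_window": [250, 550],
  "scenario": "crossover",
  "envelope_peak": 5,
  "noise_sd": 2.5,
  "kappa": 40,
  "background_template": 2,
  "trial_shift": 5,
  "trial_lambda": 15,
  "seed": 1
}
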