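{
  "version": "1.0",
  "note": "Synthetic generating values for ART-like simulations: initial component difficulties and practice-effect configuration at published effect magnitudes. Omega_delta is a package default (independence); no reference value exists.",
  "components": ["CR", "PP", "A/S", "D3", "D2", "overlay", "distortion", "fusion"],
  "alpha": [-1.585, 1.017, -0.538, 0.045, 0.213, -0.503, -0.004, -0.906],
  "practice_mode": ["fixed", "fixed", "random", "fixed", "fixed", "fixed", "random", "fixed"],
  "delta_fixed": {
    "CR": -0.090,
    "PP": 0.095,
    "D3": -0.004,
    "D2": -0.060,
    "overlay": -0.066,
    "fusion": -0.125
  },
  "mu_delta": {
    "A/S": -0.022,
    "distortion": -0.017
  },
  "sigma_delta": {
    "A/S": 0.0548,
    "distortion": 0.2049
  },
  "Omega_delta": [[1.0, 0.0], [0.0, 1.0]]
}
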