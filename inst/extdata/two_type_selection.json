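{
  "n": 2,
  "fitness": {
    "kind": "constant",
    "f_const": [1, 0]
  },
  "p0": [0.5, 0.5],
  "q": [1, 0],
  "t_span": [0, 10],
  "n_points": 201,
  "solver": {
    "rtol": 1e-08,
    "atol": 1e-10,
    "prob_floor": 1e-12,
    "max_step": "Inf"
  }
}
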