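{
  "name": "hard",
  "comment": "Hard reference chatbot machine: 4 states, 2 inputs; five probabilistic and three deterministic transition rows, state 0 predetermined (any input leads to state 2). Anchors: (2,a) -> {0:0.6, 3:0.4} with most likely next state 0; P(0|3,a)*P(3|2,a) = 0.16; state 0 always transitions to 2. Rows not pinned by published anchors are synthetic choices fixed once to match the published row-type census.",
  "states": ["0", "1", "2", "3"],
  "inputs": ["a", "b"],
  "transitions": {
    "0": {"a": {"2": 1.0}, "b": {"2": 1.0}},
    "1": {"a": {"2": 0.8, "3": 0.2}, "b": {"0": 1.0}},
    "2": {"a": {"0": 0.6, "3": 0.4}, "b": {"1": 0.7, "3": 0.3}},
    "3": {"a": {"0": 0.4, "1": 0.6}, "b": {"1": 0.5, "2": 0.5}}
  }
}
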