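{
  "name": "easy",
  "comment": "Easy reference chatbot machine: 4 states, 2 inputs; two probabilistic and six deterministic transition rows, states 0 and 1 predetermined (next state independent of input). The (2,a) row {0:0.6, 3:0.4} is the published anchor; rows not pinned by published anchors are synthetic choices fixed once to match the published row-type census.",
  "states": ["0", "1", "2", "3"],
  "inputs": ["a", "b"],
  "transitions": {
    "0": {"a": {"1": 1.0}, "b": {"1": 1.0}},
    "1": {"a": {"2": 1.0}, "b": {"2": 1.0}},
    "2": {"a": {"0": 0.6, "3": 0.4}, "b": {"3": 1.0}},
    "3": {"a": {"0": 0.5, "1": 0.5}, "b": {"0": 1.0}}
  }
}
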