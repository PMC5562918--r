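{
  "model": { "name": "frog",
             "params": { "sigma_v2": 0.1, "sigma_a2": 0.1 } },
  "sim": { "T": 50, "dt": 0.01, "seed": 1 },
  "filter": { "kind": "npf", "N": 1000, "gain": "empirical" }
}
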