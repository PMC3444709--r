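{
  "model_id": "MGMT-STP27",
  "probe_ids": ["cg12434587", "cg12981137"],
  "intercept": 4.3215,
  "coefficients": [0.5271, 0.9265],
  "covariance": null,
  "cutoff": 0.358,
  "call_rule": "methylated iff probability >= cutoff"
}
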