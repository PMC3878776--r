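{
  "network": {"enzymes": 174, "uptake": 65, "regulators": 32, "undefined": 37, "total": 308},
  "novel": {"enzymes": 82, "transporters": 22, "tfs": 32, "undefined": 37, "total": 173},
  "overlap_model_seed": {"enzymes": 63, "transporters": 5, "total": 68},
  "overlap_curated_model": {"enzymes": 84, "transporters": 41, "total": 125},
  "overlap_all_three": {"enzymes": 55, "transporters": 3}
}
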