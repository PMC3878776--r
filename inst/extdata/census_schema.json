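{
  "regulator_census": {
    "columns": ["locus_tag", "regulator_name", "class", "n_orthologs", "substrate"],
    "classes": ["HTCS", "SusR_like"]
  },
  "monosaccharide_regulons": {
    "columns": ["regulator_name", "locus_tag", "n_orthologs", "pathway", "family"]
  },
  "network_counts": {
    "blocks": ["network", "novel", "overlap_model_seed", "overlap_curated_model"]
  }
}
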