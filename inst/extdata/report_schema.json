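{
  "required": ["simulate", "qc", "de", "signature", "resampling",
               "coexpression", "projection", "recovery", "config"],
  "blocks": {
    "simulate": ["simulated", "seed", "n_samples", "n_genes"],
    "qc": ["n_excluded"],
    "de": ["ctl_acute", "ctl_chronic", "asd_acute", "asd_chronic",
           "baseline", "post_vs_ctl_acute", "post_vs_ctl_chronic"],
    "signature": ["overlap", "temporal_counts_ctl", "temporal_counts_asd"],
    "resampling": ["ctl_acute", "ctl_chronic", "asd_acute", "asd_chronic"],
    "projection": ["n_signature_genes", "shifts"],
    "recovery": ["n_baseline_de", "combined_counts"],
    "config": ["fdr_cut", "n_perm", "seed"]
  }
}
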