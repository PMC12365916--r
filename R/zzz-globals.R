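# columns referenced unquoted inside dplyr/ggplot2 verbs
utils::globalVariables(c(
  "start_bp", "end_bp", "founder", "gene", "chrom", "peak_bp", "lod",
  "ci_lo_bp", "ci_hi_bp", "peak_marker", "pos_bp", "cosine", "is_local",
  "dist_bp", "midpoint_bp", "gene_chrom", "selected", "homolog",
  "coverage", "mean_concordance", "effect", "method", "prob"
))
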