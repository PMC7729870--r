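{
  "title": "osteoid evidence report sections",
  "sections": {
    "collagen_qc": {"required": ["atomic_cn_ratio", "within_recommended", "recommended_range", "parameters"]},
    "diet_fraction": {"required": ["marine_fraction", "marine_percent", "parameters"]},
    "cluster_result": {"required": ["mahalanobis_distance", "inside_ellipse", "parameters"]},
    "calibrated_ranges": {"required": ["age_bp", "sigma", "level", "ranges", "parameters"]},
    "damage_authenticity": {"required": ["authentic", "summary", "parameters"]},
    "coverage_stats": {"required": ["breadth_pct", "mean_depth", "reference_length", "parameters"]},
    "haplogroup_call": {"required": ["best_label", "score", "expected", "found", "parameters"]},
    "parsimony_summary": {"required": ["newick", "score", "n_taxa", "mode", "parameters"]}
  }
}
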