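# Quiet R CMD check notes about data.table non-standard evaluation columns.
utils::globalVariables(c(
    ".", ".grp", ".ndet", "protein_id", "peptide_id", "fragment_id",
    "sample_id", "intensity", "quant", "condition", "contrast",
    "median_log2_fc", "q_value", "p_value", "log2_fc", "n_dynamic",
    "dynamic_contrasts", "is_specific", "removed_as_contaminant",
    "excluded", "n_enriched", "is_dynamic", "ibaq", "stoichiometry_fraction",
    "light_fraction", "origin", "best_dynamic_q"))
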