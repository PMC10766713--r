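# Campaign-level summary counts for the karst-water yeast study.
# Counts only; all ratios are recomputed by study_ratios().
key	value
n_samples	162
n_sessions	29
n_isolates	2479
n_identified_isolates	2389
n_strains	1485
n_species_rank_isolates	2339
n_species_rank_strains	1449
n_taxa_species_rank	142
n_genus_rank_isolates	50
n_genus_rank_strains	36
n_taxa_genus_rank	10
n_taxa_total	152
n_ms_isolates	2119
n_ms_species	113
n_seq_isolates	270
n_seq_species	88
n_seq_only_species	39
n_seq_only_isolates	77
n_combined_db_isolates	2283
n_combined_db_species	111
n_lost_strains	65
n_unknown_strains	25
n_unidentified_isolates	90
msi2_initial_species	65
msi2_supplemented_species	95
msi2_species_added	21
msi2_new_species_added	15
bruker_new_species	3
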