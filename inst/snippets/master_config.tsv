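workflow	type_id
NE	ne_density
NE	ne_sample_box
NE	ne_pca_variance
NE	ne_pca_scatter_12
NE	ne_pca_scatter_34
NE	ne_correlation_heatmap
NE	ne_top_genes_table
NE	ne_top_genes_violin
DE	de_counts_bar
DE	de_ma
DE	de_volcano
DE	de_sig_heatmap_clustered
DE	de_sig_heatmap_unclustered
DE	de_top_up_violin
DE	de_top_down_violin
DE	de_sig_violin
DE	de_spatial_expression
DE	de_spatial_de
DE	de_spatial_direction
DE	de_ora_all_bar
DE	de_ora_all_box
DE	de_ora_all_network
DE	de_ora_up_bar
DE	de_ora_up_box
DE	de_ora_up_network
DE	de_ora_down_bar
DE	de_ora_down_box
DE	de_ora_down_network
DE	de_ura_enriched_bar
DE	de_ura_activated_bar
DE	de_ura_inhibited_bar
DE	de_ura_network
DE	de_ura_box
DE	de_fold_rank
DE	de_p_histogram
DE	de_mean_scatter
DE	de_top_up_table
DE	de_top_down_table
DE	de_stats_table
DE	de_ora_table
DE	de_ura_table
MDE	mde_counts_bar
MDE	mde_union_heatmap_clustered
MDE	mde_union_heatmap_unclustered
MDE	mde_overlap_table
MDE	mde_overlap_bar
MDE	mde_fold_fold
MDE	mde_signature_heatmap
MDE	mde_signature_violin
MDE	mde_signature_ora_bar
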