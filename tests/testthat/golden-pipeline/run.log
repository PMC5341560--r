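seed=13
n_genes=50
min_identity=0.99
min_gap=50
round_bp=5
dedup_min_similarity=0.99
group_mode=components
de_cutoffs=p<0.05,fdr<0.01,fold>=2
reads_in=414
drclr=364
genes_resolved=50
isoform_classes=91
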