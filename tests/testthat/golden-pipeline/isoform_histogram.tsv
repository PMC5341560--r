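n_isoforms	n_genes
1	21
2	17
3	12
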