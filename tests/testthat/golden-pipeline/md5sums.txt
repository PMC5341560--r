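cf457096f4d961240bace9b9860df582  catalog.tsv
95d59effe62b4906f4ebac32e1911214  contigs.fasta
1018fbfc2c6c16627b0be97f8338ce27  de.tsv
478b26883b4ae797052c639cde2f36af  dedup_log.tsv
a7aa059fe9395baa7825c6cc5159db87  drclr.fasta
e9d948caf82a26c685c090d267ea53a5  events.bed
1531872c5fbb86cbf2d038231fad5b24  expression.tsv
edb68d0c84b68cb779278acf1f0d153f  isoform_histogram.tsv
fb4cd811cec57ceb34284dc4a0bec2a0  long_reads.fasta
a150d84b365ee1c54a2dd5777e5f6cbf  lrd.fasta
a4d5a424460e8ee78f5b17e4544f9282  map_identity.tsv
f60a22bef676d2e0a87f92ca92263147  map_partition.tsv
58a32ea9a0778f6c2421bd1b372c9ebe  root_specific_down.txt
23d104d6811615fbbd39b231e05a46dc  root_specific_up.txt
0ac6b286774b2932afe91735e852e951  run.log
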