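gene	region	intron_offset	maf	ds_ag	ds_al	ds_dg	ds_dl	dp_ag	dp_al	dp_dg	dp_dl	pangolin_gain	pangolin_gain_pos	pangolin_loss	pangolin_loss_pos	maxent_ref	maxent_alt
MED12	canonical_splice_site	-1	0	0.80	0.97	0	0	20	1	NA	NA	0.63	20	0.82	1	9.5	1.43
CCDC22	exonic	NA	0	0	0	0	0.05	NA	NA	NA	1	NA	NA	0.22	1	7.47	5.46
TMEM67	intronic	3	0	0	0	0	0.38	NA	NA	NA	-3	NA	NA	0.37	-3	5.96	-1.06
CASK	intronic	-6	0	0.9	0.13	0	0	-1	-6	NA	NA	0.84	-1	0.69	-6	7.77	3.32
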