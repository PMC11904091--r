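gene	chrom	loeuf	modes
MED12	chrX	0.071	XLD
CCDC22	chrX	0.123	XLR
CASK	chrX	0.073	XLD
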