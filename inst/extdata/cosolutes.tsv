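name	molar_mass	n_monomers	class
PEG200	200	4	peg_class
PEG400	400	9	peg_class
PEG600	600	13	peg_class
2-methoxyethanol	76.09	1	peg_class
1,2-dimethoxyethane	90.12	1	peg_class
ethylene_glycol	62.07	1	diol_class
glycerol	92.09	1	diol_class
1,3-propanediol	76.09	1	diol_class
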