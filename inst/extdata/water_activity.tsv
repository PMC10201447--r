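cosolute	wt_pct	delta_aw	note
PEG200	40	0.0489	row-mean of dG_wa/m_peg over the decomposition table
ethylene_glycol	20	0.047	reported for the worked 20 wt% EG prediction
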