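cell_cycle	panel-overlap genes annotated to cell cycle regulation	GINS2	TICRR	EZH2	CCNE2	DDIAS	ZWINT	HAUS5	CHAF1B	CDC45	NCAPD3	H2AFX	PLK1	MNS1	RRM2	TYMS	DSCC1	E2F1	RFC5	FANCA	DCLRE1A	FEN1	RFC2	CDC6	DNA2	EXO1	MYBL2	HELLS	GINS1	INCENP	LIG1	RBBP8	YEATS4	DONSON	BLM	KIF18B	KIF15	CDT1	CLSPN	MAD2L1
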