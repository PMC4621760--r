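element_id	name	pattern
S000270	ARFAT_AUXRE	TGTCTC
S000418	DRECRTCOREAT	RCCGAC
S000470	SREATMSD	TTATCC
S000453	GT1GMSCAM4	GAAAAA
S000407	MYCCONSENSUSAT	CANNTG
S000174	MYB2CONSENSUSAT	YAACKG
S000413	ABRELATERD1	ACGTG
S000439	GAREAT	TAACAAR
S000252	CIACADIANLELHC	CAANNNNATC
S000103	SEF4MOTIFGM7S	RTTTTTR
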