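motif_id	pattern
I	LxLxLx
II	GWPP[VI]
III	VKV[SA]MDGAP[YF]LRK
IV	GDVPWEMF[IV]DSC[KR]RLR
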