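gene_a	gene_b	pair_type	anchor	expr_class
GmIAA1	GmIAA30	wgd	TRUE	conserved
GmIAA3	GmIAA28	wgd	TRUE	conserved
GmIAA6	GmIAA33	expr_only	FALSE	conserved
GmIAA8	GmIAA32	wgd	TRUE	conserved
GmIAA9	GmIAA48	wgd	TRUE	conserved
GmIAA11	GmIAA56	wgd	TRUE	conserved
GmIAA13	GmIAA58	wgd	TRUE	conserved
GmIAA17	GmIAA24	wgd	TRUE	conserved
GmIAA34	GmIAA41	wgd	TRUE	conserved
GmIAA36	GmIAA63	wgd	TRUE	conserved
GmIAA37	GmIAA62	wgd	TRUE	conserved
GmIAA38	GmIAA61	wgd	TRUE	conserved
GmIAA40	GmIAA53	wgd	TRUE	conserved
GmIAA43	GmIAA54	wgd	TRUE	conserved
GmIAA44	GmIAA52	wgd	TRUE	conserved
GmIAA45	GmIAA51	wgd	TRUE	conserved
GmIAA10	GmIAA55	wgd	TRUE	diverged
GmIAA14	GmIAA59	wgd	TRUE	diverged
GmIAA15	GmIAA18	wgd	TRUE	diverged
GmIAA16	GmIAA19	wgd	TRUE	diverged
GmIAA21	GmIAA26	wgd	TRUE	diverged
GmIAA22	GmIAA27	wgd	TRUE	diverged
GmIAA39	GmIAA60	wgd	TRUE	diverged
GmIAA46	GmIAA50	wgd	TRUE	diverged
GmIAA47	GmIAA49	wgd	TRUE	none
GmIAA5	GmIAA35	wgd	TRUE	none
GmIAA2	GmIAA33	wgd	TRUE	none
GmIAA12	GmIAA20	wgd	TRUE	none
GmIAA23	GmIAA25	wgd	TRUE	none
GmIAA31	GmIAA35	wgd	TRUE	none
GmIAA6	GmIAA7	tandem	FALSE	none
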