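gene_id	chromosome	chrom_index	canonical	cluster_id	mode
GmIAA1	chr1	1	TRUE		wgd_segmental
GmIAA2	chr1	2	TRUE		wgd_segmental
GmIAA3	chr1	3	TRUE		wgd_segmental
GmIAA4	chr2	1	TRUE		transposed
GmIAA5	chr2	2	FALSE		wgd_segmental
GmIAA6	chr2	3	FALSE	GmTC1	tandem
GmIAA7	chr2	4	TRUE	GmTC1	tandem
GmIAA8	chr2	5	TRUE	GmTC1	wgd_segmental
GmIAA9	chr2	6	TRUE		wgd_segmental
GmIAA10	chr3	1	TRUE	GmTC2	wgd_segmental
GmIAA11	chr3	2	TRUE	GmTC2	wgd_segmental
GmIAA12	chr3	3	TRUE		wgd_segmental
GmIAA13	chr3	4	FALSE		wgd_segmental
GmIAA14	chr3	5	TRUE		wgd_segmental
GmIAA15	chr4	1	TRUE		wgd_segmental
GmIAA16	chr4	2	TRUE		wgd_segmental
GmIAA17	chr5	1	TRUE		wgd_segmental
GmIAA18	chr6	1	TRUE		wgd_segmental
GmIAA19	chr6	2	TRUE		wgd_segmental
GmIAA20	chr7	1	TRUE		wgd_segmental
GmIAA21	chr7	2	TRUE		wgd_segmental
GmIAA22	chr7	3	TRUE		wgd_segmental
GmIAA23	chr7	4	FALSE		wgd_segmental
GmIAA24	chr8	1	TRUE		wgd_segmental
GmIAA25	chr8	2	TRUE		wgd_segmental
GmIAA26	chr8	3	TRUE		wgd_segmental
GmIAA27	chr8	4	TRUE		wgd_segmental
GmIAA28	chr8	5	TRUE		wgd_segmental
GmIAA29	chr9	1	TRUE		transposed
GmIAA30	chr9	2	TRUE		wgd_segmental
GmIAA31	chr10	1	FALSE		wgd_segmental
GmIAA32	chr10	2	TRUE	GmTC3	wgd_segmental
GmIAA33	chr10	3	TRUE	GmTC3	wgd_segmental
GmIAA34	chr10	4	TRUE		wgd_segmental
GmIAA35	chr10	5	FALSE		wgd_segmental
GmIAA36	chr10	6	TRUE		wgd_segmental
GmIAA37	chr10	7	FALSE	GmTC4	wgd_segmental
GmIAA38	chr10	8	TRUE	GmTC4	wgd_segmental
GmIAA39	chr10	9	FALSE		wgd_segmental
GmIAA40	chr13	1	FALSE		wgd_segmental
GmIAA41	chr13	2	TRUE		wgd_segmental
GmIAA42	chr13	3	FALSE		transposed
GmIAA43	chr13	4	TRUE		wgd_segmental
GmIAA44	chr13	5	TRUE		wgd_segmental
GmIAA45	chr13	6	TRUE		wgd_segmental
GmIAA46	chr13	7	TRUE	GmTC5	wgd_segmental
GmIAA47	chr13	8	TRUE	GmTC5	wgd_segmental
GmIAA48	chr14	1	TRUE		wgd_segmental
GmIAA49	chr15	1	TRUE	GmTC6	wgd_segmental
GmIAA50	chr15	2	TRUE	GmTC6	wgd_segmental
GmIAA51	chr15	3	TRUE		wgd_segmental
GmIAA52	chr15	4	TRUE		wgd_segmental
GmIAA53	chr17	1	FALSE		wgd_segmental
GmIAA54	chr17	2	TRUE		wgd_segmental
GmIAA55	chr19	1	TRUE	GmTC7	wgd_segmental
GmIAA56	chr19	2	TRUE	GmTC7	wgd_segmental
GmIAA57	chr19	3	TRUE		dispersed
GmIAA58	chr19	4	FALSE		wgd_segmental
GmIAA59	chr19	5	TRUE		wgd_segmental
GmIAA60	chr20	1	FALSE		wgd_segmental
GmIAA61	chr20	2	TRUE	GmTC8	wgd_segmental
GmIAA62	chr20	3	TRUE	GmTC8	wgd_segmental
GmIAA63	chr20	4	TRUE		wgd_segmental
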