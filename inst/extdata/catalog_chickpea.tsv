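gene_id	chromosome	chrom_index	canonical	cluster_id	mode
CaIAA1	chr1	1	TRUE		dispersed
CaIAA2	chr2	1	TRUE		dispersed
CaIAA3	chr3	1	TRUE	CaTC1	tandem
CaIAA4	chr3	2	TRUE	CaTC1	tandem
CaIAA5	chr3	3	FALSE		dispersed
CaIAA6	chr4	1	TRUE		dispersed
CaIAA7	chr4	2	TRUE		dispersed
CaIAA8	chr4	3	TRUE		dispersed
CaIAA9	chr4	4	TRUE		dispersed
CaIAA10	chr4	5	TRUE		dispersed
CaIAA11	chr4	6	FALSE		dispersed
CaIAA12	chr4	7	FALSE		dispersed
CaIAA13	chr4	8	TRUE		dispersed
CaIAA14	chr5	1	TRUE		dispersed
CaIAA15	chr6	1	TRUE		dispersed
CaIAA16	chr6	2	FALSE		dispersed
CaIAA17	chr7	1	FALSE		dispersed
CaIAA18	chr7	2	TRUE		dispersed
CaIAA19	chr7	3	FALSE		dispersed
CaIAA20	chr7	4	TRUE		dispersed
CaIAA21	chr7	5	TRUE		dispersed
CaIAA22	chr8	1	TRUE		dispersed
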