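#%dataset_name=ExampleStudy
#%dataset_description=treated vs control at two time points
#%contrast_names=Early,Late
#%source_id_type=gene_symbol
#%organism=human
#%gene_set.Late.p_threshold=0.01
ID	M	A	P	S	M	A	P	S
TP53	1.8	9.1	0.002	5.4	0.4	9.0	0.31	1.0
MYC	-2.1	10.3	0.0005	-6.7	-1.7	10.1	0.004	-4.9
EGFR	0.9	7.6	0.04	2.5	1.5	7.8	0.008	4.2
GAPDH	0.1	12.0	0.88	0.2	-0.1	12.1	0.90	-0.1
BRCA1	-0.7	8.2	0.06	-2.1	-1.2	8.0	0.009	-3.8
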