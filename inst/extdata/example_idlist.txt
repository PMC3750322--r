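#%gene_set_desc=Example inflammatory response genes
#%id_type=gene_symbol
#%organism=human
TNF
IL6
IL1B
CXCL8
NFKB1
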