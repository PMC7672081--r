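pair	drug	mm_lines
BRAF-C10orf112	dabrafenib	7
BRAF-COL2A1	dabrafenib	6
BRAF-COL4A4	dabrafenib	5
BRAF-GPR112	dabrafenib	6
BRAF-NBEA	dabrafenib	5
BRAF-NLRP3	dabrafenib	5
BRAF-TTN	dabrafenib	9
BRAF-ZNF234	dabrafenib	5
BRAF-CSMD1	refametinib	17
BRAF-LCE3C	refametinib	25
BRAF-NBEA	refametinib	5
BRAF-C10orf112	trametinib	7
BRAF-COL2A1	trametinib	6
BRAF-CSMD1	trametinib	16
BRAF-GPR112	trametinib	6
BRAF-NBEA	trametinib	5
BRAF-PLG	trametinib	5
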