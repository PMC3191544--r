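cs_gene	at_gene	stress	r
CsWRKY18	AtWRKY22	cold	0.87
CsWRKY36	AtWRKY27	cold	0.81
CsWRKY33	AtWRKY7	cold	0.77
CsWRKY2	AtWRKY33	salt	0.75
CsWRKY14	AtWRKY15	dry	0.74
CsWRKY42	AtWRKY57	salt	0.70
CsWRKY21	AtWRKY40	cold	0.67
CsWRKY55	AtWRKY23	cold	0.66
CsWRKY2	AtWRKY33	dry	0.62
CsWRKY57	AtWRKY48	dry	0.61
CsWRKY25	AtWRKY11	cold	0.60
CsWRKY4	AtWRKY32	cold	0.52
CsWRKY57	AtWRKY48	cold	0.45
CsWRKY40	AtWRKY48	dry	0.40
CsWRKY21	AtWRKY40	dry	0.34
CsWRKY46	AtWRKY28	dry	0.14
CsWRKY40	AtWRKY48	cold	0.01
CsWRKY2	AtWRKY33	cold	-0.08
CsWRKY25	AtWRKY17	cold	-0.09
CsWRKY18	AtWRKY22	dry	-0.11
CsWRKY40	AtWRKY48	salt	-0.33
CsWRKY21	AtWRKY40	salt	-0.35
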