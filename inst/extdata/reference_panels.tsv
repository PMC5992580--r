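# Loss-of-function carrier counts for PALB2 in public reference panels, as
# reported alongside the published cross-study comparison: 1 of 503 European
# individuals (1000 Genomes phase 3) and 26 of 27173 non-Finnish European
# individuals (ExAC, non-TCGA subset).
panel	gene	carriers	size
1000G_EUR	PALB2	1	503
ExAC_NFE_nonTCGA	PALB2	26	27173
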