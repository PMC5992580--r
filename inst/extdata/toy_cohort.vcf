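##fileformat=VCFv4.2
##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations. Format: SYMBOL|Consequence|SIFT|PolyPhen|EUR_AF">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	A1	A2	U1	B1	U2
1	100	.	A	T	.	PASS	CSQ=GENE01|stop_gained|||0.001	GT	0/1	0/0	0/0	0/0	0/0
1	200	.	A	T	.	PASS	CSQ=GENE02|stop_gained|||0.2	GT	0/1	0/0	0/0	0/0	0/0
1	300	.	A	T	.	PASS	CSQ=GENE03|stop_gained|||	GT	0/0	0/0	0/1	0/0	0/0
1	400	.	A	T	.	PASS	CSQ=GENE04|frameshift_variant|||0.01	GT	0/0	0/0	0/0	1/1	0/0
1	500	.	A	T	.	PASS	CSQ=GENE05|splice_acceptor_variant|||	GT	0/0	0/1	0/0	0/0	0/0
1	600	.	A	T	.	PASS	CSQ=GENE06|splice_donor_variant|||0.049	GT	0/1	0/0	0/0	0/1	0/0
1	700	.	A	T	.	PASS	CSQ=GENE07|stop_lost|||0.05	GT	0/1	0/0	0/0	0/0	0/0
1	800	.	A	T	.	PASS	CSQ=GENE08|start_lost|||0.001	GT	./.	./.	./.	./.	./.
1	900	.	A	T	.	PASS	CSQ=GENE09|missense_variant|deleterious(0.01)|probably_damaging(0.98)|0.001	GT	0/1	0/0	0/0	0/0	0/0
1	1000	.	A	T	.	PASS	CSQ=GENE10|missense_variant|deleterious|possibly_damaging|0.001	GT	0/0	0/1	0/0	0/0	0/0
1	1100	.	A	T	.	PASS	CSQ=GENE11|missense_variant|deleterious|benign|0.001	GT	0/1	0/0	0/0	0/0	0/0
1	1200	.	A	T	.	PASS	CSQ=GENE12|missense_variant|tolerated|probably_damaging|0.001	GT	0/1	0/0	0/0	0/0	0/0
1	1300	.	A	T	.	PASS	CSQ=GENE13|missense_variant|tolerated|benign|0.001	GT	0/0	0/0	0/0	0/1	0/0
1	1400	.	A	T	.	PASS	CSQ=GENE14|missense_variant|deleterious|probably_damaging|0.1	GT	0/1	0/0	0/0	0/0	0/0
1	1500	.	A	T	.	PASS	CSQ=GENE15|missense_variant|deleterious|probably_damaging|0.001	GT	0/0	0/0	0/0	0/0	0/1
1	1600	.	A	T	.	PASS	CSQ=GENE16|missense_variant||probably_damaging|0.001	GT	0/1	0/0	0/0	0/0	0/0
1	1700	.	A	T	.	PASS	CSQ=GENE17|missense_variant|deleterious||0.001	GT	0/1	0/0	0/0	0/0	0/0
1	1800	.	A	T	.	PASS	CSQ=GENE18|inframe_deletion|||0.001	GT	0/1	0/0	0/0	0/0	0/0
1	1900	.	A	T	.	PASS	CSQ=GENE19|inframe_insertion|||0.001	GT	0/0	0/0	0/0	0/1	0/0
1	2000	.	A	T	.	PASS	CSQ=GENE20|inframe_deletion|||0.3	GT	0/1	0/0	0/0	0/0	0/0
1	2100	.	A	T	.	PASS	CSQ=GENE21|synonymous_variant|||0.001	GT	0/1	0/0	0/0	0/0	0/0
1	2200	.	A	T	.	PASS	CSQ=GENE22|intron_variant|||	GT	0/1	0/0	0/0	0/0	0/0
1	2300	.	A	T	.	PASS	CSQ=GENE23|missense_variant&splice_region_variant|deleterious|probably_damaging|0.001	GT	0/1	0/0	0/0	0/0	0/0
1	2400	.	A	T	.	PASS	CSQ=GENE24|stop_gained&splice_region_variant|||0.001	GT	0/0	0/1	0/0	0/0	0/0
1	2500	.	A	T	.	PASS	CSQ=GENE25|splice_region_variant|||0.001	GT	0/1	0/0	0/0	0/0	0/0
1	2600	.	A	T	.	PASS	CSQ=GENE26|stop_gained|||	GT	./1	0/0	0/0	0/0	0/0
1	2700	.	A	T	.	PASS	CSQ=GENE27|stop_gained|||0.001	GT	0/0	0/0	0/1	0/1	0/0
1	2800	.	A	T	.	PASS	CSQ=GENE28|frameshift_variant|||0.001	GT	0/0	0/0	0/1	0/0	0/1
1	2900	.	A	T	.	PASS	CSQ=GENE29|missense_variant|deleterious|probably_damaging|	GT	0/0	0/0	0/0	0/1	0/0
1	3000	.	A	T	.	PASS	CSQ=GENE30|missense_variant|deleterious(0.02)|probably_damaging(0.99)|0.049	GT	1/1	0/0	0/0	0/0	0/0
1	3100	.	A	T	.	PASS	CSQ=GENE31|stop_gained|tolerated|benign|0.001	GT	0/1	0/0	0/0	0/0	0/0
1	3200	.	A	T	.	PASS	CSQ=GENE32|missense_variant|deleterious|possibly_damaging|0.06	GT	0/1	0/0	0/0	0/0	0/0
1	3300	.	A	T	.	PASS	CSQ=GENE33|3_prime_UTR_variant|||0.001	GT	0/1	0/0	0/0	0/0	0/0
1	3400	.	A	T	.	PASS	CSQ=GENE34|frameshift_variant|||0.04	GT	0/0	0/1	0/1	0/0	0/0
1	3500	.	A	T	.	PASS	CSQ=GENE35|stop_lost|||0.001	GT	0/0	0/0	0/0	0/1	0/0
1	3600	.	A	T	.	PASS	CSQ=GENE36|start_lost|||0.001	GT	0/1	0/0	0/0	0/0	0/0
1	3700	.	A	T	.	PASS	CSQ=GENE37|missense_variant|tolerated|possibly_damaging|0.001	GT	0/1	0/0	0/0	0/0	0/0
1	3800	.	A	T	.	PASS	CSQ=GENE38|inframe_deletion|||	GT	0/0	0/1	0/0	0/0	0/0
1	3900	.	A	T	.	PASS	CSQ=GENE39|upstream_gene_variant|||	GT	0/0	0/0	0/0	0/1	0/0
1	4000	.	A	T	.	PASS	CSQ=GENE40|stop_gained|||0.001	GT	0/0	0/0	0/0	0/0	0/0
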