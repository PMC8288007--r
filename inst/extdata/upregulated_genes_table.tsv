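ortholog_gene_id	gene_name	n_species	pct_recovered	homeostasis	energy_production	protein_production	actin	signal_transduction	protein_binding
ENSGACG00000000075	BICD2	4	100	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
ENSGACG00000000342	zgc:56235	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000000451	NR4A1	4	100	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000001180	n/d	4	100	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000001528	n/d	3	61	FALSE	TRUE	FALSE	TRUE	FALSE	TRUE
ENSGACG00000001557	cyb561d2	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000001638	cyp2ad2-207	3	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000001993	MACF1	3	73	TRUE	FALSE	FALSE	TRUE	FALSE	TRUE
ENSGACG00000002095	fbxo45	4	99	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE
ENSGACG00000002441	bfsp2	2	100	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
ENSGACG00000002699	n/d	1	99	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000003060	n/d	3	100	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE
ENSGACG00000003199	emx2	4	100	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000003382	RASSF10	4	100	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ENSGACG00000003468	ankrd10b	4	100	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE
ENSGACG00000003738	chst2b	4	100	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000004230	RPL5	4	100	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000004583	fsta	4	100	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE
ENSGACG00000004699	rpl35a	3	99	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000005133	n/d	3	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000005383	rbm24a	3	100	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000005442	fads2	4	100	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000005784	aoc2	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000006523	RPL27A	4	99	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000006809	tdg.1	4	100	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000006865	lrp2b	3	54	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE
ENSGACG00000007184	EMP1	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000008035	mmp9	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000008464	ank1a	4	78	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE
ENSGACG00000008643	b3gnt3.4	3	99	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000009136	trpv4	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000009372	RARG	2	100	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000009865	rhag	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000010000	n/d	4	65	FALSE	TRUE	FALSE	TRUE	FALSE	FALSE
ENSGACG00000010010	EZR	4	100	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
ENSGACG00000010732	n/d	1	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000010742	fam174b	3	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000010749	slco3a1	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000011061	agmat	3	93	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000011391	dnmt3ab	4	100	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000012183	chp1	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000012484	zgc:171772	4	100	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000013112	rgl2	4	100	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ENSGACG00000013516	tmod4	4	100	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
ENSGACG00000013530	hsp90ab1	4	100	TRUE	TRUE	FALSE	FALSE	FALSE	TRUE
ENSGACG00000013597	si:ch211-107n13.1	4	100	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
ENSGACG00000013647	atp1b1a	3	100	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000014242	dpy19 l3	3	87	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000014358	FILIP1L	4	99	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000014362	n/d	1	100	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000014465	klf17	1	100	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000014559	rpl3	4	100	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000015302	rasa3	4	100	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE
ENSGACG00000015691	adma	4	100	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ENSGACG00000017200	taldo1	4	99	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000017423	hypk	4	99	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
ENSGACG00000017730	VANGL2	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000018488	n/d	4	100	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000018525	n/d	4	95	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE
ENSGACG00000019020	celsr1a	4	100	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE
ENSGACG00000019118	faah2b	2	100	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000019640	si:zfos-2326c3.2	4	76	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000019847	cct7	4	100	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
ENSGACG00000019909	ccnd2b	4	100	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
ENSGACG00000020331	ophn1	4	99	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ENSGACG00000020814	si:dkeyp-23e4.3	3	54	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
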