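doc_id	text	gene_ids	surface	expected_rs	expected_status	error_class	cited_rs
initmet.1	The Ser312Gly polymorphism was genotyped.	HSD17B1	Ser312Gly	605059	UNIQUE	init_met	
initmet.2	Carriers of the Val34Leu polymorphism were compared.	F13A1	Val34Leu	5985	UNIQUE	init_met	
initmet.3	The Val34Leu variant was analyzed.	F13A1	Val34Leu	5985	UNIQUE	init_met	
mature.1	The Val7Met polymorphism was studied.	NPPA	Val7Met	5063	UNIQUE	signal_feature	
mature.2	The I405V polymorphism was studied.	CETP	I405V	5882	UNIQUE	signal_feature	
mature.3	The Thr26Asn polymorphism was studied.	LTA	Thr26Asn	1041981	UNIQUE	signal_feature	
mature.4	The Arg80Gly polymorphism was studied.	C3	Arg80Gly	2230199	UNIQUE	signal_feature	
mature.5	The Thr715Pro polymorphism was studied.	SELP	Thr715Pro	6136	UNIQUE	signal_feature	
strand.1	The T30C polymorphism was investigated.	ESR1	T30C	2077647	UNIQUE	opposite_strand	
strand.2	The -135C>G polymorphism was investigated.	LTC4S	-135C>G	1867561	UNIQUE	opposite_strand	
strand.3	The 59G>A polymorphism was investigated.	GSTP1	59G>A	1572983	UNIQUE	opposite_strand	
strand.4	The G1287A polymorphism was investigated.	SLC6A2	G1287A	5569	UNIQUE	opposite_strand	
strand.5	The G1287A polymorphism was replicated.	SLC6A2	G1287A	5569	UNIQUE	opposite_strand	
strand.6	The C699T polymorphism was investigated.	CBS	C699T	234706	UNIQUE	opposite_strand	
strand.7	The 3823G>A polymorphism was investigated.	CYP19A1	3823G>A	4614723	UNIQUE	opposite_strand	
rstypo.1	The V660L variant (rs1042638) was associated.	PGR	V660L	1042838	UNIQUE	rs_typo	1042638
rstypo.2	The 1793G>A variant (rs2274976) was associated.	MTHFR	1793G>A	2274967	UNIQUE	rs_typo	2274976
rstypo.3	The G482S variant (rs8192673) was associated.	PPARGC1A	G482S	8192678	UNIQUE	rs_typo	8192673
rstypo.4	The T241M variant (rs861529) was associated.	XRCC3	T241M	861539	UNIQUE	rs_typo	861529
rstypo.5	The K178R variant (rs2308237) was associated.	MGMT	K178R	2308327	UNIQUE	rs_typo	2308237
dup.1	The -77T>C promoter polymorphism was typed.	ALOX5AP	-77T>C	11553656	AMBIGUOUS_DUPLICATE	duplicate	
dup.2	The mitochondrial A8618T variant was observed.	ATP6	A8618T	45566835	AMBIGUOUS_DUPLICATE	duplicate	
flip.1	The IVS3+411C>T polymorphism was studied.	CYP7A1	IVS3+411C>T	2486001	UNIQUE	direction_flip	
flip.2	The S312N substitution was typed.	LEPR	S312N	2293275	UNIQUE	direction_flip	
flip.3	The p.V432L substitution was typed.	CYP1B1	p.V432L	1056836	UNIQUE	direction_flip	
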