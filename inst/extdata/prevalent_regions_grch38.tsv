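region	coordinates	population_allele_frequency_e6	diagnostic_allele_frequency_e6	known_recessive_genes	n_coding_genes
2q13 NPHP1	chr2:109930242-110228182	5811	2616	NPHP1	3
15q11.2	chr15:21311962-23261294	2764	2287	-	14
16p12.1	chr16:21754781-22502804	584.0	627.8	OTOA,UQCRC2	11
16p11.2 proximal	chr16:29416551-30202090	507.6	1674	PRRT2,ALDOA,TBX6,CORO1A	35
17p12 HNPP	chr17:14170711-15567588	314.8	388.6	COX10,PMP22	9
16p13.11	chr16:14772948-16330433	311.0	433.5	NDE1,MYH11,ABCC6	15
1q21.1 BP3-BP4	chr1:146380249-148811725	268.2	672.6	-	15
13q12.12	chr13:22911590-24323812	201.8	104.6	SGCG,SACS,MIPEP	7
1q21 TAR	chr1:144904297-146209950	178.0	269.0	PEX11B,RBM8A,POLR3GL,HJV	22
22q11.2 LCRA-D	chr22:18530098-21214537	141.7	4499	PRODH,SLC25A1,CDC45,GP1BB,TXNRD2,TANGO2,SCARF2,PI4KA,SNAP29,LZTR1	48
10q11.21q11.23	chr10:45765081-49954967	135.3	74.73	RBP3,ERCC6,SLC18A3,CHAT	38
16p11.2 distal	chr16:28706949-29049993	137.7	254.1	TUFM,ATP2A1,CD19,LAT	11
2q13	chr2:110494056-112385043	125.8	149.5	ANAPC1,MERTK	11
7q11.23	chr7:73089294-74862006	120.0	1375	NCF1	28
2q21.1	chr2:130623447-131386379	97.33	119.6	-	9
15q13.3 BP4-BP5	chr15:30246847-32496522	99.70	896.8	FAN1,TRPM1,OTUD7A	13
2q11.2	chr2:95759114-97430329	73.60	74.73	ADRA2B,NCAPH,LMAN2L,CNNM4	24
17q12	chr17:36300613-38034442	68.86	463.4	ZNHIT3,PIGW	21
17p11.2 Smith Magenis	chr17:16777950-20450859	53.33	687.6	TNFRSF13B,ATPAF2,MYO15A,MEIF2,TOP3A,GRAP,B9D1,ALDH3A2	48
15q11q13 BP3-BP4	chr15:28580349-30417865	37.98	134.5	NSMCE3	10
3q29	chr3:195963652-197626678	21.36	194.3	TFRC,PCYT1A,TCTEX1D2,RNF168,NRROS,CEP19	23
17q11.2	chr17:30621877-32037969	21.36	149.5	-	14
15q11 PWS-AS BP1-BP3	chr15:21976318-28537425	19.89	687.6	OCA2,HERC2	27
15q11 PWS-AS BP2-BP3	chr15:23247414-28447477	19.89	657.7	OCA2,HERC2	17
22q11.2 LCRD-H	chr22:21206521-24255497	11.87	59.79	IGLL1	45
8p23.1	chr8:7596999-12344083	9.495	134.5	RP1L1,FDFT1	50
10q23	chr10:79733715-87254783	7.121	59.79	MAT1A,CDHR1	31
15q24 BPA-BPC	chr15:72628218-75278711	2.374	74.73	BBS4,STRA6,EDC3,MPI,COX5A	40
15q11q13 BP3-BP5	chr15:28569118-32447357	2.374	59.79	NSMCE3,FAN1,TRPM1,OTUD7A	21
7q11.23 distal	chr7:75456184-76629927	2.374	29.89	POR,MDH2	19
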