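gene	region	deletion_frequency	aggregate_burden	hom_viable
NPHP1	2q13 NPHP1	5.811e-3	6.82e-3	TRUE
PMP22	17p12 HNPP	3.148e-4	3.54e-4	FALSE
ERCC6	10q11.21q11.23	1.353e-4	1.17e-3	FALSE
COX10	17p12 HNPP	3.148e-4	5.05e-4	FALSE
ALDOA	16p11.2 proximal	5.076e-4	5.64e-4	FALSE
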