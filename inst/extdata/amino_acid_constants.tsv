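code3	code1	C	H	N	O	S	hydropathy	pK	charge_class
Ala	A	3	7	1	2	0	1.8	NA	none
Arg	R	6	14	4	2	0	-4.5	12.0	basic
Asn	N	4	8	2	3	0	-3.5	NA	none
Asp	D	4	7	1	4	0	-3.5	4.05	acidic
Cys	C	3	7	1	2	1	2.5	9.0	acidic
Gln	Q	5	10	2	3	0	-3.5	NA	none
Glu	E	5	9	1	4	0	-3.5	4.45	acidic
Gly	G	2	5	1	2	0	-0.4	NA	none
His	H	6	9	3	2	0	-3.2	5.98	basic
Ile	I	6	13	1	2	0	4.5	NA	none
Leu	L	6	13	1	2	0	3.8	NA	none
Lys	K	6	14	2	2	0	-3.9	10.0	basic
Met	M	5	11	1	2	1	1.9	NA	none
Phe	F	9	11	1	2	0	2.8	NA	none
Pro	P	5	9	1	2	0	-1.6	NA	none
Ser	S	3	7	1	3	0	-0.8	NA	none
Thr	T	4	9	1	3	0	-0.7	NA	none
Trp	W	11	12	2	2	0	-0.9	NA	none
Tyr	Y	9	11	1	3	0	-1.3	10.0	acidic
Val	V	5	11	1	2	0	4.2	NA	none
Nterm	NA	0	0	0	0	0	NA	7.5	basic
Cterm	NA	0	0	0	0	0	NA	3.55	acidic
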