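gene	mf_score
SNAI2	0.000834
KIF4A	0.000778
ECT2	0.000756
MYO5A	0.000743
TOP2A	0.000552
RAD51	0.000498
AURKA	0.000443
SMYD3	0.000436
RUVBL1	0.000428
PPT1	0.000417
DNMT3B	0.000388
FZD2	0.000358
LPCAT1	0.000269
RFC4	0.000253
SERPINH1	0.000246
FOXM1	0.000239
ACD	0.000200
UMPS	0.000194
PLOD3	0.000194
SLC39A6	0.000191
HJURP	0.000190
SLC39A14	0.000182
SPAG5	0.000179
KPNA2	0.000127
MTHFD2	0.000123
CBX3	0.000111
FNDC3B	0.000104
HOXB7	9.81E-05
PTDSS1	9.77E-05
FSCN1	9.74E-05
DUSP12	8.57E-05
CALU	8.46E-05
E2F6	7.00E-05
CERS2	6.43E-05
HMGB3	5.01E-05
MFAP2	4.49E-05
MINPP1	4.07E-05
GTF2E1	4.02E-05
WDHD1	3.62E-05
TRAM2	2.81E-05
NEMP1	0
THAP12	0
C20orf27	0
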