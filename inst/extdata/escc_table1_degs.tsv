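gene	abs_logFC	fdr
HOXB7	2.058	1.69E-07
SMYD3	2.237	2.36E-07
ECT2	5.174	3.19E-07
CBX3	3.540	4.69E-07
AURKA	2.981	7.46E-07
WDHD1	3.398	9.01E-07
MTHFD2	3.201	2.87E-06
KIF4A	2.436	5.72E-06
DUSP12	3.427	5.94E-06
FNDC3B	2.085	6.18E-06
RFC4	2.147	6.29E-06
HJURP	2.969	6.51E-06
SERPINH1	3.521	6.53E-06
RAD51	2.885	6.70E-06
FZD2	3.203	6.98E-06
MFAP2	3.131	7.10E-06
LPCAT1	2.765	8.08E-06
HMGB3	2.120	8.38E-06
FOXM1	2.641	8.82E-06
TRAM2	2.599	9.10E-06
GTF2E1	2.078	9.16E-06
NEMP1	3.884	9.29E-05
SNAI2	3.645	9.31E-06
FSCN1	2.073	9.45E-06
DNMT3B	2.098	9.79E-06
RUVBL1	2.263	1.72E-05
SLC39A14	2.006	1.79E-05
PPT1	2.214	1.82E-05
TOP2A	2.784	2.12E-05
MYO5A	2.393	3.73E-05
UMPS	2.261	3.93E-05
MINPP1	2.078	3.96E-05
SPAG5	2.317	4.06E-05
SLC39A6	2.463	4.11E-05
KPNA2	2.060	4.45E-05
THAP12	2.671	6.25E-05
CERS2	3.065	8.44E-05
PLOD3	2.821	9.61E-05
PTDSS1	2.257	9.98E-05
ACD	2.042	1.00E-04
C20orf27	2.826	2.89E-04
E2F6	2.111	3.06E-04
CALU	2.383	3.17E-04
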