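bin	count	percent
0.4-0.5	380	41.35
>0.5-0.6	232	25.24
>0.6-0.7	168	18.28
>0.7-0.8	84	9.14
>0.8-0.9	30	3.26
>0.9-1.0	25	2.72
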