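term	mean_auc	n_genes
Cell cycle checkpoint	0.91648	39
Mitotic sister chromatid segregation	0.91597	29
Regulation of cyclin-dependent protein serine/threonine kinase activity	0.88779	32
Reproduction	0.84575	23
DNA damage checkpoint	0.84231	26
G1/S transition of mitotic cell cycle	0.84194	34
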