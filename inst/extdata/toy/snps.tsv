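gene_id	coding_length_bp	snp_count
g001	2079	5
g002	1470	3
g003	1041	2
g004	2325	7
g005	1269	5
g006	1110	4
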