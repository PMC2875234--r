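gene_id	group	has_paralog
g001	maternal	TRUE
g002	maternal	FALSE
g003	paternal	TRUE
g004	paternal	TRUE
g005	background	TRUE
g006	background	TRUE
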