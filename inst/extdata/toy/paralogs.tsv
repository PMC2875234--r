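gene_id	paralog_id	rank	paralog_chromosome	protein_identity
g001	g001_p1	1	21	53.5656062365579
g003	g003_p1	1	X	60.7238580449025
g003	g003_p2	2	13	58.6717393523583
g003	g003_p3	3	6	42.3409593513345
g004	g004_p1	1	7	65.0882816154031
g004	g004_p2	2	18	60.2624911115572
g004	g004_p3	3	4	39.7761719152952
g005	g005_p1	1	15	81.3555915971999
g006	g006_p1	1	22	54.047349589291
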