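gene_id	species_a	species_b	protein_identity	cdna_identity	gap_count	ka	ks
g001	human	mouse	70	77.7777777777778	0	0.150713754950065	0.704279152050069
g001	human	rat	66.6666666666667	77.7777777777778	0	0.169976298109075	0.598594457977756
g001	mouse	rat	93.3333333333333	90	0	0.0314182062818701	0.350505383869689
g002	human	mouse	86.6666666666667	87.7777777777778	0	0.0618907677660026	0.397971188296628
g002	human	rat	86.6666666666667	87.7777777777778	0	0.0701810354190845	0.357997252003356
g002	mouse	rat	96.6666666666667	91.1111111111111	0	0.0302307926160697	0.329524994837884
g003	human	mouse	86.6666666666667	86.6666666666667	0	0.0624547911592669	0.460448958754831
g003	human	rat	90	86.6666666666667	0	0.0464664705016049	0.538780307629216
g003	mouse	rat	96.6666666666667	95.5555555555556	0	0.0152289496205592	0.138856824851697
g004	human	mouse	86.6666666666667	81.1111111111111	0	0.0644691974650136	0.869891935431621
g004	human	rat	90	82.2222222222222	0	0.0473841762161487	0.90976697988439
g004	mouse	rat	93.3333333333333	94.4444444444444	0	0.0396393436337332	0.106184079998703
g005	human	mouse	96.6666666666667	94.4444444444444	0	0.0146703943908702	0.217732646143538
g005	human	rat	96.6666666666667	94.4444444444444	0	0.0146703943908702	0.217732646143538
g005	mouse	rat	100	97.7777777777778	0	0	0.101851155869296
g006	human	mouse	80	80	0	0.104446550500131	0.80283105877606
g006	human	rat	76.6666666666667	80	0	0.121889197123331	0.687218048905616
g006	mouse	rat	96.6666666666667	95.5555555555556	0	0.0150380977841708	0.144444830336838
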