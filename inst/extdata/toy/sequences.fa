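>g001|human
AATGGCCGTCAGACCGGGGGAGTGATGCCTACGGAATCACCAGTGCCCATGAGCTACAGAGCGGCTAACC
TTATCCCGCACGAGCCCCGA
>g001|mouse
AATGGCCCTCGGGCCGGGGGAGTAATGTCTAAGGAGTCACCCGTACTGATGAGCTACAGAGGAGCATATC
TTGTCCCGCACGAACCTCGG
>g001|rat
AATGGCCCTCGAGCCGGGGGAGTAATGTCGATGGAGTCACCACTACTGATGAGTTACAGAGGGGCTTATC
TTGTCCCGCACGAACCTCGA
>g001|cow
AATGGGCCCCAGGCCGGGAGCGTAATGTCTAACGAGTTACCAGTACTGATGAGCTACAGAGGTGCGTATC
TAGTCCCGCACGAGCCTCGG
>g002|human
ATGTTGTCCGCGCCACTTTTTCCTTTTTACCTATGCTTTACTCAGACTTGGTGTCGGATTCTGCGCTCTC
GGTTTAGACGCCGCGACTGC
>g002|mouse
ACGTTGTCCGCGCCACTGTTTCCTTTTTACTTGTGCTTTACTCAAACTTGGTGTCCAATTCTGCGCTCTC
GTTTTAGACCGCACGACTGC
>g002|rat
ACATTGTCCGCGCCACTGTTTCCTTTTTACTTGTGCTTTACCCAGACTTGGTGTCCAATCCTGCGCTCTC
GGTTTAGAGGCCACGACTGC
>g002|cow
ACGTTGTCCGCCCCTCTATCTCCTTTTTATGTGTGCATTACCCAGACCTGGTGTCCCATCTTGTGCTCAC
GGTTTAGACCTCATGACTGC
>g003|human
GGCACCACCTGTAGACAGAGTGACTGGATCTCGGGGACTAGTAAGCTAGTGTTCCCTGTGAAACCTGTAC
CCACGGTTGAAGGTTCCCTC
>g003|mouse
GGCACCACATGTAGACAGAGTGACAGGATCTCTGAGACTAGTAAACTGGTATTTCCCGTGAGACCAGTAC
TCACGGTTGAAGGTTCCCTC
>g003|rat
GGCACCACATGTAGACAGAGTGACAGGATCTCTGAGACTAGTAAGCTGGTATTTCCCGTGAGACCAGTAC
CCACGGTAGAAGGTTCCCTG
>g003|cow
GGCACTACGTGTAGACAGAGCGACTGGATCTCTGAGACTGGTAAGCTATTGTTCCCCGGGAAGCCGGTAA
CCACGGTCGAAGGTTCTCTC
>g004|human
TACATTTTATTCCCGCCGCCTACGGTATTCCGGCTCTGTACCCATATCTGGTATATTACCCCTCCAATAT
ATAGAGTTCATCGGCTCACT
>g004|mouse
TACATCCTGTTCCCGCCACCCACAGTGATCCGACTATGTAACCATGTTTGGTATATCACCCCCCCAATAT
ATAGAGTTCAGCGGCTCACA
>g004|rat
TACATCCTGTTCCCGCCACCCACAGTGATCCGACTTTGTAACCATATGTGGTATATCACCCCCCCAATAT
ATAGAGTTCATCGACTCACA
>g004|cow
TACATTTTGTTTCCACCACCTACAGTAATTCGACTCTGTAACCATATATGGTATATTACTCCGCCGACAC
ATAGAGTTCATCGCCTCACT
>g005|human
TGGGTAATACTTGGGATTTTCAGGAACTTAACGAGGTCCTGCGAGCCTCTCAGTCGCCCCTCCGATTTAT
TGGAGTACGGCTGTGTTAGG
>g005|mouse
TGGGTAATACTTGGGATTTTCAGGAATTTAACGAGGTCTTGCGAGCCTCTGAGTCGCCCCTCCGATTTAT
TGGAATACGGCTGTGATAGG
>g005|rat
TGGGTAATACTTGGGATTTTCAGGAATTTAACGAGGTCTTGCGAGCCTCTGAGTCGCCCCTCCGATTTGT
TGGAGTACGGCTGTGATAGG
>g005|cow
TGGGTAATACTTGGGATTTTCAGGAATTTAACGAGGTCGTGCGAGCCCCTGAGTCGTCCCTCGGAATTAG
TGGAGTACGACTGGGATAGG
>g006|human
CCCTGGATTAGCGCTCTGAACCGGAAGGGGCCTCCACATTTGCTAGTTGCATTCCAGCTATTCTCGGAAC
TGTGTAAGGGTCTGCTCCTC
>g006|mouse
CCGAGGATTAGCGATTTGAACCGGAAGGGGCCTCCACCCCTGCCAGTCGCATTTCAGCCATTTTCAGAAC
TGTGCAAAGAACTCCTCCTC
>g006|rat
CCGAGGATTAGCGATTTGAACCGGACGGGGCCTCCACCCTTGCCAGTAGCATTTCAGCCATTTTCAGAAC
TGTGCAAAGAACTTCTCCTC
>g006|cow
CCCAGGATAAGCGATCTGAACCGAAAGGGGCCTCCCCCATTGCCTGTCGCTTTTCAGCCATTTCCAGAAC
TGTGTAAGGAATTACTCCTC
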