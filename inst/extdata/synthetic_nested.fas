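>A
AGTCGTCAGCCTCCACGATAGCCTGTTGACGTCAGGCAACCTTGTGCGTGGTCATAGCTA
>B
GGCAATCTAACTCTTGTGAAGATATGTCAACCATCTAAAGGGGAAAAGGCAAGAGGGGCG
>C
CGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCACTCGGTGCCTCTTGCTCTT
>D
CTGTAAAGTCACCCACCTCTTACTCCTTCGCAGCAAGAAAGGGAGGCCGAGAACGCAAGG
>E
CCTCTGGCGCAAAGCGTACCTATATCCACTGACTTTCACGAATATTTCTTACTATGACAA
>F
TTTTATCCGCGAGTCAGAAGCCTCACGCTGGTATCTCAGACACATAAAGCACCATAGGTG
>G
GAGAAATGGGTACGGACAAGGACGATGTCACCCTATTTGCAAACAGCGCTGTAGACTCCG
>H
AATGACCTTTTTCAACTTTGTCCGCAATAATGTAACCCACCTATTTTGCCCTGGCACATC
>I
AAGACGAACCGGTATAAAACAACATAAACGTTGAACCACTATGCTCTGCTTCATTTAATC
>J
TTGCGGATTCCAAATCAAGGAGACGATATCACCGATGTCGTAATGACCGAGAACTAAACA
>K
CAATCTCATTTCCCGACGGGAACTAAATACTGGCACGACAAAGTGCTAGGTTCGTAGCCT
>L
GACTTCCCGTGTGGTCGGGCGCAGGAACAACATCCTTGATTCCGCTGGCGCGTGTCCCGA
>M
AATGTTGGTAGCGCAACCACCTTTGTTTTTGCCATGCCACCGGCGCCCAAAGGGTATACT
>N
GGTCACTTTGTGACAGAACTTAGTGTCACGAATTGTCAGGTCGCTCTGAACTGTACCGGC
>O
TAAAAGAATCGTACCCATGATTCGATCCCGTGGCGAGATGTGCTTAAATGGCCCGCGCAA
>P
CTGGCCAAGTTTACTTCTACGACGGAAGACGACAAAGGGTCCTCCCACCTGTAATCAGTA
>Q
ACTGATTCATACATTGTCCCTTTCGTGGCCTAGTCAGGCATTGTCAAGTGAGCATCCTCA
>R
CCAGTGTTAATGTGATTAATTGGGCCGAGAGGCCCGGATATACTGATTAGCGGACCTGTA
>S
GTACGTTCCATGGTCCGTTTTACCTGGGACTAGCACAGCGCGAGTACTAAAAGGAACTAT
>T
GTAAGATGGACAACGACCGGGCCTTTAACCCCTCACTGGTGCCTCGATGTATGATTGATT
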