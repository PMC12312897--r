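>COI
TTAATTCCGTAATTATTATAAAGTACCTTATGGCCCCCCCTGGAGTACAGGAGCGAAGCCGCTTCCACCA
CACCCCCAATTGTGTACGTAGAAGAAGTGGCGGTTAGCTCGGCGGATCTGTCGGTCCGACAGACTCCGGC
GAATGTGAGATGCGGGTCTGCCCAGTGAAGTTGTACGGCGCGCGATCGAGTCTCCTCATTACACTTATTT
CCACGAACCTTCCATACATCATAGGTTACTAGCGGCTCAGAAGGGTATCTTATCAGCAACCTAGACTGTG
CCTACCAGATAGCAATCGCGACTATTGGGGTATATTTCATCCACGGCGCACTAGGTCGATAGGCGCCCCC
TTTGGCACAGCTGGATGATGGTCTCTAGCAAGAGTGGAGAGTCCAACCTGTACCCAACCTTACTCGCTAC
GGCCTTCTCGCAAACAACCTTCAAGTTGTTACCGCATAATGCAGGCTAGTATTGTTGGTGCTCTTTGTTT
GCGATCTTTATTTATATGGGTCAACTCGGGAGGCGGAATGTTTTTTCCTTATGAGGATGATACCACCGTA
TTATTTGACTCTCTCTTTAACGGCTCCGTAGGTGTCGCCACATTCCCCTAATATAGCCGTGTCAGCCCAA
GTGGACCAGGAGCAAAAGCTGCCCTCGTCCCTTTTTCGCTACGCAATTAACCGCGGAGCGGACAAAGAGT
AGTGGACAGCGTGACTCACGAGATCTGGGGCGAATCCGCACCGAACCAGCAAACCGACGCTGAAAATAGT
TATTGAGAAAGGTGCCTAGTAGTTCCAGTTGCGACACCTGAAAGCGACAATTCAGCGACGCGAGTCTATC
GGAACACATATAAATCCAGTACAGGAACCTCGTTTGGCACCGTTTTGCGGTACACGAGCATATTTTACAT
CGACCCCCTAGGTATCACCAATCTGTCACACTAGGACCACGATCTAGCGAGGCGAGACCAGGGGCCCGAG
ACTCAAACCCAGGAGGAAGAAATGCTGCCGCGCTTCAATCCCTTCGATGTAAGGGATAAAGTACGTGTGC
GGTGCGTTCACAAACGGCCACGCCGATCAGCACATATGGGTTTGAACACCTGAAATACGACGACGCTACG
GAGATGCTCGATCACATAAGGTCTTTCGGCTATGGCTGGGAGCGTTGTCCCGTCGGTAAGACTCCGTTGA
CCGAGATTCCAACAACCGACAGGCAGCCTTCTCCGTCAGCAATGGATCCATAAGCGTGGAGGCACTCTAA
TGCAGGGAATATATCTCAGTGCGTGAGGGCGGGTCTGATGGAATATCCCGATGAAAAGTGGTGCAAGGGG
TATCAATGCCAGCGAAATCGAACTACTACATAGTCTCGCGCTTACGCTACCAGCTACTTGCTCTTTAGCC
CTCCCGTGGGAGCAACCCGCAGAACAAGCACGGGACCTACAACCCGATACGATATCAAAATTTACCACCA
GC
>TpiGenomic
CCGGACTGAAGGTTATCGCTTGTCTCCCCTCCAGCACGTACGTTAACACTAGCGTGCCAGATAGGAGTAC
ATAGTCTATCCTGAGTGGCCCAAAAGGGCTGCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGG
GATGTGGGTTGTTTGCGAAAACCTCAACACCACCATATAGAACAGAGTTTACCTCAACTGGTATCAGGGG
AACAAGATTCCTTAGAAAATGTTAGTACGTCCAGGGAGACGGTGCGTCCGATATTTAATAACGCGAGAAC
GTGGCGAGCGTAATACAATCAGAGAGAGAAGCGACGCATTCATTAGCACATGAATATGGAACGAAGAATC
TCATATTAGGTCATTTCATCTCTTCGCACCTACTAAACGGCCCATTGATGTAGAGCATAGTACGAACTAG
ACAGAGTAAACCCCCACTTAAGCTAACGGGTTTGAGTGTATGCTGCGCTCAGAAGTCCATTGTTCCGATC
CAACTGGCATGCGGACCAGAAAAGGCTGCCTATCTTGTGTCGATATAGGATTGAAGTTGCGTTTTCGGAT
CCACGTGTAAATGAATCGCCACCAACGACTACTCAAGGACGTATGTCTTATGTCCGTTCTCGACTCTGAC
ACATGCTTAACCAGCCGTAGAAACTCACCCTGGGAGTGAGATCGAGCTGCTAGCATCTCCGCGGCAAATC
TCGCGGGGGTTGTCAGCGAATGCTTCCGC
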