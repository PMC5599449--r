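>TS0001
TTCTTACGTGTTGGTGTAACAGCTTGTGAGAAACGGTCTAGGGAGTAGTAACCGTTACCGAGAGAGATAGGTGTTTAGAA
GATCACCCTGCTCGGTGGCCGTTGATTATTCGAGGGAAGTTTGCCTGTGGTCAGCGACCCGGCCGTTGACGCTGAGGAAA
TTTAGGGTCTTGTTTCACGCCCCTGAAGACCGTGCCGGAGTTGGTCTAGGGGAATTCAAACGTTTTATCACCATCAAAAG
TTGTAATCGGGGAGCAAGACGGGATCCAATCGTCCCTACCCTGAACCGGCAACTAGAGTACAACTAAGTTATCGTGTTTC
ACTGTCTCTGGCCCAATTGCTGGCTCACTGATAATATTAGCACGTATCTGAGGAGTCGTCATTTTTTACCCGGATATTAA
CGCAGTGCAGCATAGGCGGGACCTACTACGAGATCCGCGGTGAGTGTGGCCTCATGGGGTAACAGATCCTAGGTTGCATG
GTCGTGGCCGAATGAGGAAAGTAGCTGGACTTAAACGCGCCCGGAAGAGCGACTTTCTCCTCACAATTTTACACCACAGA
GTATTACATATAGGCGCTAGATGATCGGAGGTTACCCCAATGTATTTCCAGGCTCGGCAAACTAAGTCTCTAGGTATGTC
CCCGTAATATCCTTTCCGGCTCCGAGTTACAGACTTCCCTTCTGCGAAGACTAGATCCAGTCCAGTTACGTTAAGTTAAA
CATTGGTACCATACTGTGGTTTAGAGTATAGCATTCCGATCGTGAGATTGCGCATAGAACATGCCCCCTATATGCCTGCC
TTATCAAAGGGGGAGTCGCTGTGCACTGCCAACTGGATGGGGAGTGTCCCACATTGCGGAGTCCCCGCTCGCCGACCTCA
TCTCGCGAATATACGTACGGGCAGGGCTGCGGAACGCCGTGTCCGAACGTCCATATACAAGGCTGGCCAGTAAATGTCCC
AGGACCGTAATCTAGATTCTGAGTAAGTTAGAGCTAGGCTCGCGCCGAACAAACATACCCGATGCGTATTGGCATACATA
TCTTTTGCTCGCGTGGCCCACTGCCTCTTAGGGCCCCTTTCATGCTGTCTTTGAGAAGCTCTACCCCTGCTATTGGCAGA
TCGTAACTACCTGTTTGCAAGAGCAAGAATCCGCCGCGTCGCAATCTCCCATAATTAGCTTTTATTATACTCAACTGATA
TCACCCCATTCCGAGGTATTTCACACGGTGAGCTTGAGTCCGGGCACAACTGTGCAGGAAATCTTATCGTGCGGGGAACC
GCCGGGTGTTTGGTAGGGCACCGTCCTGGACAGGCAAAACTGATGCCTAAGTCCACACCCCTTCTTGCGTCACCACCGGC
GCCACGGCGTGTCCGGAATCCAGCCTCCCTCACGCAGCTCACGGTTTATACTTCTCACATGCGGTCCGTCCTTCGTAAGG
ATCGGTAATAACTCCGTCGCCTTGACAAAACCGAGATGTCCCTTACGATCCTGGTCCTCA
>TS0002
CCGGTGGCGTCCGTCAAACAAGGCCGTGGTTGAGCTGACCGCGGCCCAGGCTTCTACATAGCCTTGCTCTGGTGCCTTCT
GGTCGTTGAAACGATTCCCACTAAGTAACGGAAGTCGTAGGACATACATCATACTCACTTTGACTCCAATGAGCCCCCGA
GGCTGACTCGACTTATCTGAAACCTTCGCCGAAAAGGTAGCTGGGGGCAAATATTTCTGTGCTACGAGTCGGGGAAGCGG
AATCATCTTACAATACGAACTAGAGAAAATCGCGAGACAGGCGTATCGATCTGCCACGCCTTGCACCGCGCGTGTGACAC
CTCTTTAGGGACTATGCCTTGGATGCAGCATGCGACGGGTGCCCTGGAATGGCCCGTGGGCTCCGGTATAAGCACGATAT
TTTCCGAAGCCCGGCCTTGTTCGCGTCAATCAGGGCGGCGCGGCCCAAGGCCGGGCCTAAATATCTCACAGGGTCTTAGA
AAAGGATTCATGGAACGCAACGAATTCCTACGTCTAATCGACAGTTCACGGGTCACCACTACACCATCGTCAAACTCAAT
CACATGAGTAGGATCCAGTGGGTTTGGGACAATAGCAATGACCAGTACTTTGGTCCGTGACTACTCCGATGGTCGTGTAC
GCGAAGAGTCGCTAGAATCAAACTCTGACTACTCCCTTGGGGACTCCGCGTTGCGTTACGTGCGTGTGTTGGTTGGCAAA
TCTGCGTACGCCTGGTTGGGAAATTGAAAATCACCAGCTGAGAGTTTTAGCTGCAGGACGGACTATCAAGAAACCGGCGT
CGGCAGTGGGCAGCAGTCCGGAGGCCGTTTAGCCGGGGATCCTCGGCATCCTCTTACTGCGTAAGCTTTCCTGTTTAATG
GAATGCTGTGCGCACAGTACCGCAATTTATCAGCTATGTCAGTGACACAACATACAAGTTTACTGTGTCCGAATCCCATC
AGTCTTGCTAAGGGCGTGAATCACTCTGTCCGAACGGCTTGTGGCCGTTTGTACCAACGGTAGGCTAGATATCCGTAACA
TTAATCCACGTAGGTAGCCCAGATACGTATGCCTCTATCCGTATCATCACATAGCTGAAATTATTTTCTGCATAGTAATC
CACCTTCGGATGGTCTGGCAACTCCGCGTCAGGCCGATAATATCGTCCTTCCTTGTAATAATACTTGTATTATATGGCAT
TCCATCTATACCAAACACGATTCGTACAGTAGTTAACTATTGTAACGGCTCCGCAAGTGGTGTATAAGACCGATGAACCC
TACGACTGGATAACCAGGCGTTAGGTCTCTGTTCCAGAAAGCTGCAGAGTGCCAAGACATTTGTAACAGTGGGGTCGCGA
CGGAAGACAGTACCCGTTGTCTTCGTGCGAACTGCGGTTGGTCATCCCACGAAAACCGTCCCGCTTAAGAGGTGCGGCCC
TTGAGTGTCGCGTTCCCAATAGGGTTGTATACTCTTCATTGCAAGCGACTTCTCTCCTCT
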