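>chr_demo synthetic demo reference
CAAAAATCTTCGTCTGCTCATAAGAGGGCTGGGCGCGGATAAATGTGTTCGATGTAACCTGCTCAGCAAT
GCTGGAGCGGCACGGACCACATGCATTGTTAGAGCAACAGGCCAAGTTCACGCGGTAGCGATAGACGCGT
CGCGTATCACGGAGTACTCGCAAATGAAGGGCATTCCCTGTATCTTCGGCAAATATATATAAGGTCGGAG
GTAGAATCCTAGTGTAGAGAGGCCGGCGTTAAGTTTATGTCGAGAGACCCACGACGCGACGAGACCATTT
ACGATTGAAATCTACAATCGGTGCTCGCCAAGTCTAGACCCTAGCTGACCCGTGATCAGTTCGACATTAA
CCGATTGTTTCGTTTGTTTTAGTCTTCAGTATATTCTGAGCGAAATTCACTAGCGGTGTATGAGCCCAAG
TGCACCGAGCTGAATTTTTGGAGTCGCCCCAACAAAAGACAATATGTCAATACGCACAGCCCTCAGTGAG
AATTCTTCCATGCCCTAATTAGTAAGAATCGGGCCATCCTTGCTCAATAGAACCTGTATTCCGCTCACAT
GAACATGCTCTGAGTCCGTGTTTAGACTTGCGTAACCTATGTGCATGCGTGGCCCTCGGCATCACTCCCT
CTCGGAGCCTTTCTATGTACCAGCCGCTCACAAGGAATGTCGGTTAGCGACTCCGGTGATCTCGGCCGCG
GAGCAAGCAGCAAAGAAAGTTCACGCCGTCTAACTAACCCAGAGGAGTTTCAGAGGTACGCATCCAGGCG
TCCAAACCGAGAGGACTCTGGATGGCGTAGGCCAGGATAACCTGCAAAGTTTAGAGAAAGCACCGCCGAT
TACATGTGACCCTTGCAATGTCCAAAGACGTGTTGAGGTCTCCCGATATGGCCTCTCGGGGGCGAGCAAC
GATCGAGCCCGAATCCCCCACTCCTACTACCGCGATTAATTGTTCTAGGGTATAGTGTACTGTGGGAAAT
GAACATACAGGGCGCACAGCGTCGAGGTCTACCGACTAGCAAGGGCGATCCAATCCCCTGTCACCCACTA
GTCCGAGAGGTAAGAAGGCCCTTTGACAGACCTCCATAACGTCCACTACCCAGGTGACGGCGCAGGTTGT
CTTTCGACCGGCTCGCACCACCTCGGGGGTCGGTGCTTTCGAACATAGGAGGTACGCCCCCGCTGTGGGA
ATAGCGTCACCTCTCCCTGTCTCTGGCTAGCTGGTACTGAAAGGCTGATCCTCGCCGTTTACGGGGAACC
GCGATAAAAGGTTGACCCTGTCAGTTCGCAATACGAGGATGCCCCTAAACCCACCTGTCACAAAGTAGCA
TGACATATGTTTTGACGCGACTCAGGAGCGGGACCACCGGATCTATGACCCCTCAGGTACAAGTCACGGG
GGTAAGATGGATCCCCCATGGCGGACTGGCGACCTACCTCTAATCTTTGAGCTATTCTGGTGGCTAAGAA
TGCTTAATGTCAATATTACGCAATAAGAGCCGAGTCACTAGTTTTAACACTCGGCCTAGCACATGCCTCT
AGGAACTATGCTGGTGCTCTGTGTTTAGAAGACTACCGGAAGACGCAGTACACTCACTTACACAGCGCTC
CTTGACCATCCTCAGCATAGGAGGCTTTGTCCTGCGCAATATCATTGTCCTTGCAAAGAATCCAGACTCG
AGCATAATGGCATGGTAAGTGCTCATTGTCAAGTTGGTTTGTGGCAATGTCTATTATTCTGCTACATTAC
GACTTCCAGGTCACATCGGTTAGGAGGTAGTGCGAGTTGTTTACGTGACTCCTCGGGACCGGATTGGGAC
TTGAGACGTGTGTCAGCCGGAAGTTTACACTTTGGCCGGCAGAAGGTCGTTCGTACGGGCAGAGCGTAGA
TGTTTGTTTCAGTACTAATGCCTTAAGTATTCCTGCCGGACAGTTTGACCTTTGTCCTATTATAGGGTTG
CACTTCAACGGTTATATTATCACGCCATGCCCATATCGATTACGCTGAGCGCCAAATTTGCCATTAACGA
TTGCTAGACGTTGGCAGCCGTAGGAATCGGCTAGAACTCAAGTCTTGCTCTGATGTACAGGTCTCGACGT
GCATAACTCAGCACATGAAGGTGAGGCTAACAATTACCAGTAAGTGGGCGGACGGCGAGGCCACTGGTCC
GTTGGCCTGAATTATACGGCATACAGCGAGGGGCGCACACCACCTTGACTTCCGTCGTTGCAGCCGGCGT
CGAGCACAACGGTGCCTTAAGATCCTATGTTTACAGGATGGTCTGAGCTGTGAGATTAGTTTCCTGAAAA
GAAAGACCGTGATGGCTTAATTACTACCCCTTTCGGCAGTGCTAGTTACCTGCCCAATTGTTATAAGCAG
TATCCATCAAACGTGCCGTG
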