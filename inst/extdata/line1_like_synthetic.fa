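>LINE1_like_synthetic length=2000 note=synthetic_seeded_random
CGAGCTTAAGCTTAAAATTCAGGATCCCCGGTCCTCTTACGGAAAGTATAAGTTGCATCTCCCCTGATCACGGTCCCACC
ACCCTAAGATTTAGACCAAGAAATGATTTTGGAGTCGATGTTGACGCTCTTGTCCTTTTCTACCGCATTAGTTGTTGATT
TGCTTGACTAAGGGGGACGGTATCTCTACAGAGTCTTTTCAAGCCACAGCATTGTAAGGGTAACGACTAACTACCTGGTC
GGCCTGATGCTAAAAAACATGTCGCGAGGCCATATTATGTTCTATGAAGGGATGATTAGCAGAAGACCTGGGCGCGGTAG
CCACGCGACAATCAGCCCGGAGCACCCGTGCTGACAGTCATATCCTTTTCCAGCGCTTTCAGCCGTCCTTCTTGCGATGG
GCGTCACAAATGCAGGGTAACAAAGTCGGAGGACAAGAGCACGAACGAGGTTGGGACGTCCTCACTTACCGCTATAGTTC
ATTTATTATGCAATCCCCTTGTCTCCCCCGCTGTACGGCACTAGACTCCCTTGCCAGGGAGACCACTTCCTCCCTGAACC
CCGGGATGACGTACGTGGTATCCGAGACGAATCGGTTTCATAATCCCCTTTCCGAGATTGTCAACATAAAGGTTGGATTG
GCGCCCTTTCACTCGAGAACAGCTGAGCACAGCACTTTACTAGTCAGGATTGGAAAATTGGAATTCCGGATAGCCTGTTG
TTCGGCATTGGATCATAGCGCGCAGTTATTACATATAGTTTCCCAATGACTAGTAGTTGCCGCCTTACATGGAACATGTG
ACACTCTGAGGCCTAGGGCTTCGGATTGTGAGTGAAGATGACTCACCCAAAAGTATTAAGACTAAATAGATTATCCACTG
TGACCTGTCTTATGGGGATGTGGTCATTTTGCTCGATTATATTTTTCGCTTAATATTCTGCATCGCGACCCTCTGGTCAG
ATCTTCTAAGTCCGTTAGAATCCTGCGGTTACCAGGGCTAAGAATGAAGCTGTAGTGTTCTTCTGCCTTCATGTTACTGA
ACACGAGCGCGTCGAAAAGAGAGAACGATTCCCCTGTTGTGTGCACTAGAGCAAGAGCTTAAAAGTTAGTCCCCAGCGCC
TTGCTTCGTCGCATAAAGGCAATTCGTCCTAGTAAACCGCCTACCTTGGCCCGAGATGGCGTCAGAAGAACGCTTAGAAA
TCGGGGGACGCTCCAAGCACAAGGGCAACTGTTCGTGCCCCTCCGAGCAGTATGACCGTCGCAACATGATAGTCTTTACA
TGATTGGTAATAGGGGGTACTCCAATGCGCGGGCCATAAAATGTTTTGCGGTTACTGGAGTATTCTTAGAGGTTTAGCTT
TTATTGGAGTAGTAATAACTGAAATCCATATATTGCCCTGTGTAGTCCCTCTATCCCCATACTGTCGTGGCTTTCGATGC
TTCCGATCTACTCACTAACTTTACAGACGCGACCAGGCTCTATGAACATTTCCTAACCAGGGTAGACGTGGAAGCAACCG
ATGACTGATGCGTTCCGCACATGTGATCTCTCACTCCTACCCACTTACCAGTTTGTAATACCAGCCGTACAGCAGAAGCT
CCACGCTCCACAGCCAAAGGCTGCTCATCGTTCCACCAGACGCAAGGTGGCCACAATAGGTTCTCGGCTGGCCCCCTCTA
CACGGCACTTATGTAATCTAATCCAGGATCTCAGAAGGACAAGAGGCGACTACCTAACGTTTAAGCTAATGTTTCTTTAG
TGGTTATTTTCTATGTCATTGGACGCCCGGGAATGTGAACCACGTCGCGCTACAGGAGTGCCTAACGAAAGCGGCGTCAT
ATACCGCAGGCACCGAGGCTAATATTGCTCAGAGGACCCTTAGTCCTTTAATACCAACGTCTAATTCGAGTAAGAATTCT
GAAGCAACCGCTAAGCACCCTATCAACGAGATTGATTTACGGTCAAGGAACGTCAGATGTGTGAGTCGGATGCTTGTGCT
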