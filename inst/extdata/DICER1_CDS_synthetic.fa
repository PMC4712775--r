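>NM_177438_CDS_synthetic_surrogate 1922-codon DICER1-like coding sequence (synthetic stand-in, see package docs)
ATGACCTCTGACTCCGGGCTAGAGGATTCGCTGGCTCTTAGTAAGATGGAACGAAATAAG
CGTCAAGCCCTCTGTTCGTTGAGGGAGAAGTGTTGGGTGCTCGCGGGGGCGAAGAAAGTT
CCCGAAACAAGAAACTCCATGATCCTGAGTTCTGATCCGTGTGACTTGCAAGATCCTCAG
ATATGTGATGCAAAGAAAATCAACTCGGATAATGATATCAGTTCTGAGGCGAAGAAAATT
GACCGTTGCCCCAGCAGGAACCGTCTTCTGTGCAACGTCCCCTCGGGCCACCCAAAAATT
CCTCAATCCCTCGTGATGTCACGAACGGTTAAATCGGACCCCGAACACGGATCTAATGGG
GTCGGACCGCAATCTTATGGGAACAATCCCCAGGAAACAAAAGTCCAGGACACGGAACAC
AGGGAGTCTATCATTTATGCAACATCCTTCATGGCTTTGCGGGGCATGGGATCGAGGATG
CATAAAAGTACATACAGAAAAAAACAGCTAGAGTCGCTGCTGGTGCGTGGCGTTGGATCG
CCCTCATATGACGCACGTACACAAAACTGTATTCAAACGTGCAACAAAGACATGCATCAG
GACCGGCCTAGGACTGAGAGACCGACTCATGTGAACTGCAAGAAAGTCTCGCGCGGAGCT
AGACACACTTCTAAGGAGCCCAAAGGCTGCGTTCCTCTTGGCAAACACAGGGCGCCTGGC
TTTCCCCGGTGCTTTGATAAAGTTCCGCGATACCTGCAACGATTGAGTTACAGTAAGGCC
GTTGTCCCAAAATTATTTGACAGACGAGAATACAAATGTGGACACATTAGCCTTACACTT
GTCGAGGACGTACACCCACCGGAGGTCGCATTGCATCTGCTGAACCATCCCGCTACAAAT
TGTATCCTCCGAAGACAATTGGATGGAGCACGCGACGAGGTATGCCAAACGTCCACCATT
CGAAGTCGAACGGGGACCCATAAACAGAAGCAACGAGCATGTCTCGTGTCATCCATTGGT
GATCGTCAGCGAGAGGCACTGTGCGCCTTCCCTAAGACTCCTCGATCGAACGTTGTGTCG
CTTTATGTTCAGTGCGGCGGCGCTAGTTCGATATGTGGCCGGTATGGAGTCCTACAGCCA
TCGACGTTATTTCAAACGAATCGACTCTCTAGGCCTGGAGGCTCTCCGATTGAAGGGTGG
GTTGTAGACCATGGGACAGCGCCTGTGTCGTCAACGCAAGTAAGAAGCCAAGGAAGCCCC
CGGGGGTCGTTAAATGATCAGACCCGCATGGTATCGATACTGCCTTTTGAATTCTATGCC
GGAAAGCTTAGCGGGCCGTGCGGACGAGACCTTTTTTTCGAAGTCGGGGGCGCGAGTCGA
TGTAAGGATATGAGCGCGTATCCTTGCAAGACTAGAGCTACCCAGAGCCGACTAGGTGCC
ATTCGGAAGCCTACGTGTAGATGCAAGAGAGGGGGGTCTCAAATGGAGGAAGTGAGGCAG
AAGATTTCGACTCAACTATTGAGGCTGGGTAGCGCCACGGGAATGCAGCACAATTTGCGC
CACCTTTATTGCGAAATACCACCGAGACATCGTCAATTTGTTATGAACAAAAGCACAATC
ACTCCGACCGTATCTGAAAAAAAGCGGGAATCGCACTTTAGACATCCCAGGACCGAGGTC
AAGCTAGAACAGAGAATCTTTGTTGCGACCTCTGGGAAGTTGCTGGCCCAGGAAAAAGCT
CAGATCCCCAATGGAAATAGTCCAATGACGCAAAAGCAGTCTTTGACGAAATATCGATTT
AATGTCTTAAGCGAAACTCTTCAACATTCCCTAGTGGGGGCTATCGTGACGAAGCCTAAG
ACACGTACTTTCTCTATGCATTTGTTGCGTGGTAAAGTACCCTGTGGTTTGTTCAGAAGA
AGATCGGATGTGTCCAAGCCCGTCAACCATCTCAAATCGCCATTTCGACTGAACATAGGC
AAAAATAAGGGGGGTCTTAGCCAGGGTTCGATAGAGGATGAGTCCCTGCTCAGTCTCGTG
CATGAGACGTCGGAGATACAGGGGATGGAAAAGCGAATAAATCTCTTGATCGATTTCTTC
TCTACCGTGAATTCAGGAGTGTTCTGTTCCGATTACTGCACAAGAGACACTCCATGTCGT
ATTCGGCTGTTCTCCACTGTGGTTTGTGAAGCTGCGCTAATCCGCTCGAGGAACCCGCAT
TATGCGCCACCGCTGCGTATTCGAGGGGATCATAGACTCATCCAATCAGAGCACGACCCG
ACGCGAAGTACATGTCCACATGAAATTAGTGAAGACGATCTGAATTCTCAACCTTTGACA
GAAAGATTTGACGACACGGATACTGTGTTAGCTTGGCGACAGTTCATTTCCTCATGCTCT
CATCTCCCATATGCTCTGGCCTCGTTTCCATTCAGCGAGTTGGATGCGGTAACAGTGCCG
CTAGTTGTGATGGGGATTCTAGCGGAGAATCCCCGTTCGCAGCATGGTACTGCGGACTAC
AAAGTTGCACGAGCTAAAAACCGGAAGTTACTCATTCGACGTCATAAGACAGACCCGTTG
ATCGCCAAACCCACTGCTGCAAGGCTAGCGCTACAAAAGATTACGACATGTCGATCTCTG
AATAGTTATGTGCCGGAGCGTTGCAATGTACCGAGAGATCAAGGTCTTTTTACCCAACGT
TACCACCCATGCGATAGACAAGATTGCGTTAGAAACGAGGGAGTAGTACGAAAGGTAATC
GGCAATCGAGTGCTCTGTTGTCGGTCGTATGGAACCCAAATTGCCACAATCCAAAAATCT
ACCTTGCGTCGCAAGCAGTATGGAAAGCGAGACGAATTCAGCACCCAGACTAGTACTCGT
GCATCGAATGAAAAATTGGTAAATCGACTCGAGATTTACAGTAAACTCATTCTTCTGGGT
GATGACAAATGCGTCCCACCTGACTTGTCAGACGAGTCGGACACCGTCAAAGTACGGAAG
AGAGGAGCCAAAGATGACGTACCTGTCTTTGACGTTTGTCCGGCGTCGACCTTTTCCTTG
GAACACACGCAGAGGCACGCCGATCCAGGTGAAAAGAGAGGGGGAGAAACCATCTGTATT
GTTTTGATTCAAGAGGGAAAAATATCGGGAACACTTTGCCTTGCGACTAAATCTGGCACT
CAGTGCGCAACATGCCAACCTCAGCTGAATACCTTGCAGAATCCATCCTCCGCCAAAGCG
ATCGTCAGGATTAGCCTACGATCTGTAACCCAAGCACGTAAAGTTAAATGTAAAGAACCG
TCGTCGAACCGGCACTCGGGACAGTGTAACACCAGGAGCCCCCACCCGTGTCAGGTAAGG
AAGGTAGAAACCCAAACATTGGGACGGATGGCCCGCATCAATGGCACAACGTCCAGGGCA
AACCGCTGCGGCTCAAGGAGTCTTCATAGCCAGAATGGACGGAACGAGTGCAGAAAGGGC
TGCGGAAGCGGAGGGAGATTGTTGAGAGCCGACGAGGCCGAGCGCGAGACTCAACCCCGA
TGCGCACCGCATGAGGGAACGACGATTTGCCGAGTTCTGATTGTCTCCTCCCGGTCAAAC
CATAAATGCCTGACATGTGCCGTATGCACAACCTATAAAGCGCGGTCCTTGGTACTTACG
ATTGCTCCTATGAGTGGATGCCAACTGATCCCACTCATTTGTAAAGTACTTAAAGTACCG
TTACACAAGACAATTCAGATCGTCATCGTTAATGATCCTCTCAGATTGACGATCCATTGG
AACAACCACATTTCGGAAGTTGTACAAGGAGACCTGATAAGATGCGTAAAAAAATTGATA
CTAGTCGAGCAGGGGGACGATTTTCATGAGGACAGTGACCCCACAAGCGGTGCTAGTTCG
AAGAAACAGCTCGCGCGAGAGAAATCGCCTCGTCGCTTGCAGTACGTGAGGATTAGACTT
AAAATATGGACGGCCGCGTGTACGGAGTCCGCTAGCCTCGTAACGCTACCCGCGACTCGC
GAGGTGAAAGAACCGCAGAATAAAACCACCGTACAGAGTGCACCATCTAAAGGAGTGAAC
CATTCCGGTAAAGACAATAAAAAGAATTGGCGACAGCTGAAAAGTAATCACTCTCTCGTG
CTGGCATGTACCCACCCGTCCAACATCTCTTTTGAACCCGCGGCCTTGCCTGTAGATAAT
TTTGCAAGGGATGACCGCGCTACCTCGGCCATACTAATAGACTGCGGTGACCTCTTTGGC
TTCTTCGCATTGTTTCACTGCGATGCCCATGCCGCAACAGTTAAAGACTCTGTAAACTCG
TGTACCGACCCTAAACCGCGGCCAACTTTACGGGCGGCCCGAACATTCTGTGAACCGTCC
CGTCGTAGGCGGGAGTGCGTACGAAGACCCTGCTGCTACTGTTGTAAGGGCGGCCCGCGA
ATATCAACACGATCCCAAGGGGGGAAGCTCGTTCTGGGATGGGGCGTCCGCTCGCCCCCC
CCGGTAACGTGTTTAACTTCGTCGTCGGCGGGAGGACAGCAAACGGGACTGATGCTCCAT
CTGGAGGATTTCACTAAACCTCCTCAGTGTATTGCTTTGCGTATGAACTATTTCTCGAAT
CCGCACAACATAGGTGGCGCAGCACTCTCAGCTATCAGCTCGCCCACTCGACGGGACTCG
TGTCTTTCCAAGCTCTCTTGCGTTCCGTCCTCTCGCGTCCAAGAGATTGTAATCTGCAAG
TTGCTACTGGAGCTTGGACGACACTCCGGGTTCAGTCCAAGTACCTGTTTCTCGAAGTTG
TCGCCGAAAATTGGGATGAACCGTGAGGTAGGCGAGTATCGCGGGATAGCGCTCTTGCTC
AAGAACCGAGGACTAGAAACTCAATCGGAGCGCACTAATGTCCGGGGTACACATTGTGGT
GTAGACTTGTGCTTTAGGGGTTGCCCGCTCGGACCTAAACCCACGCGTTCCAAGGTATGC
ACGGAGTCCTCTCAGAGTTCGTTTCGCGCCACTAGATTGGATTGTGTGATGATTAGCGTC
GGTAATCTTCTCTCGTCCCAGTGCCAGTCGCGTAATGACTGTGAATCTATTTCAAGTAAG
TGTTGGGAACATGAATCGGGAGGAGATCAACATAAGGATGGCCAAAGCGCTTCGCGAATT
CAACCAATCGGCGCGGGGGGCGTTCAGGACTCGTCATCGAATGAAGCAGCAACAGCATCG
GTGAAGGACGCCGAGGTTAAAGGCATCCGCCATATTCCGCAACATCACCGACGTGTGATA
TTGGTTACTGTCTGTACAAGTCTCTCTGGCCGCGAGAAATCGAAGAAAGATCTTCTCTTT
AGAACGTCGCAGCCCACCAGGTCTCGCAGATTCGTGGCGTTCGAAGAGGGTAGCGGTTCG
ATTACCCAGCGCTGCATGACTACTGGGGATACCCCAGAACACACGGTGGAAGCACTACTT
CTGGATCTGGTTTCGGAAAAGAGTTTTTGTAGCCATAAAGAATCCTCTCTGAGATCGGCT
GCGACCCGATTTCGTAGTAACCGAATTAGAATTGCCCCTTCAGTTGGACCGAGAGTACTG
ACGGGCAAGAATGGAAGGGAAGCCGATTTTATTCGTTTGCCATTCGTAAGCAGTAGAAAA
ATAGGACATCAGCCACGATGCAAACGAAACGGCGTCGCCATCCTGGAGTCCGGCCCTTTT
AAGTCGAGCGTGCGCGAATCGTATCATAAACTTCGCGGACCCACTCCGATGTACGTCGGG
ATCGCATGA
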