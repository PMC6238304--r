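>CYP2D6_INT2_synthetic synthetic 1101 bp stand-in for the CYP2D6 intron-2 amplicon
GGAATTCCGAAGGGCGGCGCATTTGCGTCTCACATACTGGGGCCAGTCAACCTCGTCTGC
AATGGCCGGATGGGCAACGGCTGGAGGTAAGCCAAGGACAGCGGATACAGGACCATAGAC
CGTTATAAGGCCCGCCTCAAGATAGTGCGGTTTGCCCAAAGTTGGACCCTTTGACCTTTC
CATTACCCAGTAACCCGTCTGAACCCGTGCTGAGGGTAGCCTCCGGATCGTCGTAAATTC
TATGTCTAGAGTTATGCCCTTGTTGGTCGGAGACTTTGACAACTAATTCCATAACAATCC
TACTGTATACTTGGGAGGGTATTTGAAGAATTTACCCGTCCTAGCCACCAACTTGGGCAT
AGGGATGTGAACCGATTTAACCAGCAGCTTATGAGTCGGCGGGGACTGGTCCACGGATAT
GGCCCATTGTTAACCTTCTTTCCCTAACTAGGTTCGCACACCTGTCTGGACGAGGTCGCG
TCACCCGAGCCGACGACATGATGGCGGCGGGCGTCCTACACCACAGACCGAAGATTCCGC
TGTTAAGGCGTATCGCATATGGCTGTGCTGACCAATCTTGTGACGTAGTCTATCTGGACC
GGCATCGGCCACCCGAGCCCCTGGGTGCACCCGGGTTTTTGGTCCCCCTCCCACTTGAGG
GCTTCCAGCTTCGTTCTCCTGATAACTTAAAAAAAAAGCTTTTGCCCGAGCCCCCTACCT
GGACAATATGGAGCATGTCTCATAAGCACGACGCTCTGAAAGTCCTGGAGCCTCCGTGCG
CCGCGGGCAAATTAATGTGGTGAGGACACCGGAAGCCAAGGTGTACATGGAGGCGATCCC
CCGGATAGCATAGTAGGACGATCGTAACCCGAACTGGGAGGCACGGTGGGTTTACACTCT
TAGTGAGATCAGAGGTCGTTCCTCCCGGAGCCCGCCGTCAAGGCACTTCACCCGCGCTAG
AGGGGCGGAGCATCGTCACTAGGGGCACTTCGGCGTTTTGTGGTTCCGGCTGCACAGCGC
TGCGTTTCCTGAGAGGAGTGTGATGCGCAGCGTTCTTTCTTCCGACCAATGGCGTACGGA
TCCGGCCATGACCCCGCCTCC
>CYP2D7_INT2_synthetic synthetic pseudogene reference, ~93% identity to CYP2D6_INT2_synthetic
GGAATTCCGAAGGGCGGCGAATTCGCGTCTCACATACTGGTGCCAGTCAACCTCGTCTGC
AATAACCGGTGGGACAAGCGCCGGAGGTAAGCCAAGGACAGCGAATACGGGATCATAGGC
CGTTATAAGGCCAGCCTCAACATAGTGCGGTTAGCCCAAAGTTGGACTTTTTGACCTTCC
CATTACCCAGTAACCCGTCTGAACCCGTGCTCAGGGAAGCCTCCGGATCGTCTTAAATTC
TATGTCTAGAGTTATGCCCTTATTGGTAGGAGACTGTGACACCTAATGCCATAACAGTCC
TACTGTATACTTGGGAGGGTATTTGAAGAGTTTACCCGTCCTAGCCACCAACTTGGGCAT
AGGGATGTGAACCGATTTAACCAGCAGCTTATGAGTCGGCGGGGACTGGTCCACGGATAT
GGCCCATTGTTAACCTTCTTTCCCTAGCTGGGTTCGCACACCTGTCGGGACGACGTCGCG
TCACCCGAGCCGGCGACAGGATGGCGCCCGGCGTGCTATACCACAGACCCAAGATTCCGC
TGTTTAGGCGTATCGCCTATGGCTCTGCTGACCAATCTTGTGACGTAGTGTATCTGGACC
GGCATCGGCCACCCGAGCCCCTGGGTGCACCCGGGTTTTTGGTCCCCCTCCCACTTGAGG
GCTTCCAGCTTCGTTCTCCTTATCATTTAAAAAACAAGCATTTGCCATAGCCCCCTACCT
GGATAATATGGAGCATGTCTCATAAGCACGACGCTCTGAAAGTCCTAGAGCCTCCGTGCG
CCGCGGGCAAATTAATGTGGTGCGGACACCGGAAGCCAAGGTGTACATGGAGGCGATCCC
CCGGATAGGATATTAGGCCCAGCGTAATCCGAGCTGGGTGGCACGGTGGGTGTCCACCCT
TAGTGAGATCAGAGGTCGTCCCTCACGGAGCCCGTCGTCAAGGCACTTCCCCCGCGCTAC
AGGGGCGGCGCGTCGTCACTAGGGGCACTTCGGCGTTTTGTGGTTCCGGCTGCACATCGC
TGCGTTTCCTGAGAGAAGTGTGATGCGCAGCGTTCTTTCTTCCGACCGATGGCGTACGGA
TCCGGCCATGACCCCGCCTCC
>CYP2D8_INT2_synthetic synthetic pseudogene reference, ~91% identity to CYP2D6_INT2_synthetic
GGAATTCCGTAGGGCGTCGCATTTAAGTCTCACATACGGGTGCCAGTCAACCTCGTCTGC
AATGGCGGGATGGACAACGTCTGGAGGTAAGCCAAGGACAGCGGATAGAGGACCATAGAC
CGTTATACGGCAGGTCTCAAGATAGTGCGGTTTGCCCAAAGTTGGACCCTTTGACCTTTC
CTTTATCCAGAAACCCGTCTGAACCCTTGCTGAGGGTAGCCCCCAGATCGTCGTAAATTC
TATGTCTAGAGTTATGCCCTTGTTGGTCGGCGACTTTGACAACTCACTCTATACCTATCC
TACTGTATAGTTGGGAGGGTATTTGAAGAATTTACCCGACTTAGCCACCACCTTGGGGAT
TGGGATTTGAAACTATTTAAGCAGCAGCTTATGAGTCGGCGGGCACTGGTCAACGGCTAT
GGCCCATTTTTAACCTTCTTTCTCTAACTAGGTTCGCACACCTGACTGGACGAGGTCGCG
TCTCTCGAGCCGACGACATCATGGCGGCGCGAGTCCTGCACTACAGACCGAAGAATCCGC
TGATAAGGCGTATCGCATACGGCTGTGCTGACCGATCTTGTGACGTACTCTAACTGGACA
GTCCTCTGCCACCCGAGCCCCTGGGTGCACCCGGGCTTTTGGTCCCCCTCGCACTTGTGG
GCTTCCATCTTCGTTCTCCTGATAACTTAAAAGAAAAGGTTTTGCCCGAGCCCCCTGCCT
GGACAATATGGCGCCTGCCTCATAAGCACGACGCCCTGAAAGTCCTGGAGCCTCCGTGCG
CCGCGGCCAAATTAATGTGGTGAGGACACCGGCAGCCAAGGTGGACATGGAAGCGATCCC
CCGGATAGCAAAGTAGGACGATCGTAACCCGAACTGGGAGGCTCGGTGGGTTTACATTCT
GAGTGTGATCAGACGTCGTTCCTCCCGGAGTCCGCCGTCAAGGCTCTTCACCCGCGCTAG
AGTGGCTGAGCATCGTCACTAAGGGCACTCCGCCCTCTTGTGGATCCGGCTGCACAGCTC
AGCGTTTCCTTGTAGCAGTGTGATGCGCAGCCTTCTTTCTTACGACCAATGGCGTACGGA
TCCGGCCATCACCCCGCCTCC
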