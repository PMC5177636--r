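>pseudo16S_synthetic synthetic 16S-like reference (not a real accession)
AGAGTTTGATCCTGGCTCAGTCAGACTGTCAGGAAATCGGTCACTTAACATAAGGAGGTACTTCACAAAA
CACGCAACTTCCTAGAGGTCTATTCAAATTAATGGGGCGACAGGAAGTCATCATCAATTCGCAGACTATT
CTTAAAGCGTACCGAATAACCGGACTACTTTCTAATTATACATCCCACCTGATGAGAACAAGTATCCTCG
GGGGACTGACTGACACAGCGTACCCTCTCGCTGCTCGTTTTGACGTTGCCCAGCTTTTGAATGATTACAG
TCGCCAGACGTTGATGTCTCACAACTGTAGGCCCGGTAAGGCCTGCGAACCTGTTAAAGCTATTTGCCAC
TGCAGGTCGTTCCTGTCTACCAGGGAACACATCAATGGCTGGAATAGTTCCGAGCGGTGCAGGGAACTAG
GATGCCCACGGGTGCCACATCGACCCCGTAACCCAACGCATCAGCGTTCATAGCCGATGCTGTTACAGAC
TTTCTCCGGACGCCTTCTTGGCGACGCTTTAGCATGTAGCGGCCATCCACGTGTGACTTTTAAGGCCCCC
GAGGCCAAAACCTTTCCCGCGGGTAAGTCGATAGCCTATCACATTGGAAAGGCATACTACCATTGCCGAG
CCGAATATGGTACAGTTACGTGAAGCGAGAAAGAGCTTAGGGTATACCTGTTCGCGACTCGGAATAACGG
TTGGGGAGTGCGCCTGTGGCAATGGGTCAGGATCTTCAGCCGCAATCCTAATCGCTATGGGCGGATTATA
ACGGTTGAGAGATTTACCGTGGCCGAAACACTTCGTCACTCACACGCGAAGTGGTTCTGCTCTCGAAGCT
TCTCCTGCGCGAGGTCACGTTGCAAAGGGGTCTAGTTGACCTTGGCGTCCGTGACTTAACGTACATAAGC
GCTGGTCCTGCTGGGTGTGCCACGTTATCGCCTAGCTATTGCGGGCATTTCTTGCCAGCTCCGGGCCTTC
AACGGTCTTCTCATCCTTCGTCGACCAAAGTCAACGACGGTCGCCGGGGTCCTGCCCTAAACCACGCGCA
GAAGTGGAAAAACTGCTTCGCCTGCGCATGACTTTTCACGCAGGGGTCCTACGAGCCCACCGATCTCTCA
TGATACAGGCGCAGTGCAGGCACCAAAAAATGTTTTGGCGCTTTTATATCGCGCCGCAGCGTCAGTGTGA
TAGAAACCATAACCGGGTCCTCGCAGTGCAGATTCTTTTTCTTTGACAGTATTTACCTAATTGAGCGTAG
CACTGGACCATAAACCCGGCAGCTGAACCCATCTCCGGTTTGGGCTGTTCTAAAGCGGAGCGTGGAAGTC
AGTCAGGGCTGCTACTTGTTTCAGCCACAGTCCAGACTGCGTCTAGTGTTTCAAACTTACACGGACACAC
CCACGAAGAGCTAAGGTCCCTGGGTGCACGGGTGTATTTCGGTGAGATTGAGCCGTCTCTCAAGTCGTAA
CAAGGTAACC
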