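>rRNA_synthetic_01
TCAAGTAGAGTGTTTTTAGTACGCCTAAGGAGAGCATTTTATTAATGGCCGTTAGCACCCACTATATTTCAATATAAGTAGTTACTAATTGGGGCTACCTGATAAATCTGTTTTCTCATCAGAGCGCTTTG
>rRNA_synthetic_02
TATTTAGATCTCTCTCATTGTACTTTACTTCAAGTCTAATATCTTTGGCGTATAGAAGAGTTCAGACTGTATTTGAAATGTTTAACTATTAATCGTGAAGAGAGCATCTATAATAGGATTTCATGAACGCCGATACAGCG
>rRNA_synthetic_03
GAATGCCAAAGAATTTATCGAAGTTTTTCAACCCTGATAATGTCACTCGATAACAGTATCGATTAGAAACATAAGATATATCTCAATTAAATCTAACGCTACGAGTCCCACATTGAATAATACAGCTGGCGAACGTATGGGATGAA
>rRNA_synthetic_04
CCGCCATGAATCCAAATTAGACAAAAAACATATGCAGAAGCTAAAAAACTGTACGATGGTTTAGCTTCTGACTTAAAATCAACCTAATTTAGCGTACATTATACACTCATCGGGAATATTGTGGACGAATGAAAACTGCC
>rRNA_synthetic_05
CTACACTCTCATGTACGAATGGGCAAATCTTTCGCGGGGCTCAGCACATATGTCATTTAAATGCTTGTGGTTATATTGCTAGCTACTCAACTAGCGTCAGTCATTTTCCAGGTAGACTTGCAGGTGATTCTCTT
>tRNA_synthetic_01
TTAGCGTGATGCACAAAACACTTTCATACGCGTCAAGGTGACCTAAACTGAGCCTTTTAGGCGGCGCGTCTTTAAACTTCGCC
>tRNA_synthetic_02
ACCATAGTCCGTTTCGCAATTATCATATGGATTGCGTGACAACGTTTGGTGTAAGACTAAAGGAGTCAAAGG
>tRNA_synthetic_03
GCATAATAACGTTACACTTACCAAGGATCTTGGCGGGGTGGATCTCAAATGGAGACGTAAGTTCATAGAGAAGTCATCCCTACGGT
>tRNA_synthetic_04
AGGGTACGCATCTACTGTGATCCAAACTCATAATTCGGTGTTCGACGGTATTTGTTGGTCTAATCTCGATTCCTGAGGTAATCTC
>tRNA_synthetic_05
ACGCGGACTAATTAGAACCAATGAGTAGCATAGACATCATCTATTTTGAAGTTACCTGTTAGGACATTATGGATATACAAATTGCTCTAG
>snRNA_synthetic_01
ATCATCTGGATCACGTGCTATTCGCTATTGCTATGCCCTATGTAATCACCTACTAGCAAATTAGTTTCCAGCCGGTATCGGAGAACTAAACGTCACGAACTAG
>snRNA_synthetic_02
GTGTTGTAGTTAAGAAAAGGGATTGACATTCTCACACTTGACGTTTAAAGTAATCTACGGAACTCGTCGTGCTTATGTAAATATCGGAGCGGGTAACTCGAAA
>snRNA_synthetic_03
TACCTGATAGGTAATAAGCATTAAGGTTGGTTAAATGGCCAACGAAACGCTTTATAGGATAACAAATAAATATCGAAGTTTGACCTTAAGACGGAACATAGACCCACTTAAGATTTGCACTAGA
>snRNA_synthetic_04
CTTGCACACTTGATCCAGACATGAATCTTGACAAGAAGCTCTATATCCGGGTCTATTTTTAATCCATAGATAATTCTAATTCCTGTCAACAAGCTACGCAGGA
>snRNA_synthetic_05
TCCTTGTTCTCTCACGATAATCGCCCTAAACAAAATTGCACAAGAGGTCAACAGAGGAAGGATGAGACCATAGCTCTAATTAAATCAATGATCAACAGTCCAAGATGGGTCCCTCTTTTTT
>miRNA_synthetic_01
CTTGCCCGGGCCAAAGGTATCCGATTACATTTTAATTCGGAATATAAAAAAGATTCAGCAACTCAGATATTGTTGAGTAC
>miRNA_synthetic_02
GATTTACCGGCCAGATTAATTAAGCGAAAATATGCATTATTAGTTAGACCTGTAATCAATATGTGACAA
>miRNA_synthetic_03
CATAACCTTTACAATAACAATCCCAGGAATAAGTAACTCCCGTAATCGTAGTCATCTCGTATCACCAAAGGACATTTGC
>miRNA_synthetic_04
AGGGACAGAAGCTCAAGTGTATCTAAGAGTCAGACCATGCATCGCCAGGATAGTCAATCTAACGATGTATGCTATTGACG
>miRNA_synthetic_05
GGATAACGTATGACCTCGTTTCGACGATTGTAGAAAAAACGATCTCTGATTATTGTTTGGC
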