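>peak_chr1_182315_182542
AGCAGGACAGACTGTGACTAGGCGAAAGAACTGATTTAGAATCTGCCTCCCAAGATCTGGCCGCGAGGGTTAGTCTTTCT
CCTAAGCCGATGCTTGTGGTCTTGGTAAATTAGAAGCAAATGCTCAATGGAATTCTCAACTGGGGGAGATGTAACTGAAT
CATTTTGATCTGAGTCACCTTGCTTAGTTGTTATTTTTTTTTTATTTTCTGCTAGGGATGAGCCAGTTCTCCTGACGAGG
GCAGAGGACCCTCACGCTAATAGCGCACGTCGCGTAAACATTCACTGTAGTTTGACACCCGCGTAGGCCGGGTTCTGTAC
GACTATGTGGCTTGTATCTTATTGCTCTAACCACCTCTAATACGCCACCTTCACTGGAAAATGTTTAAACCCTGCCACAG
>peak_chr1_185535_185752
CTCGCCCTTCAGCGACTTGGATACATACCGGGCTTCCTTCCCGTACCTTATTTATTCCGCATTAAGCGGTAATTACGTGG
TAGGAAGCATTTCATCCAGCTGGCAATCGCGAGTGACGGCTCCCTTATGTATGCGCTGAGTGGAACGCGTATTATTGCTT
GTGAGGACATACCGCCTCCTGGCCAACAACGGGTAGTCGTTGGCATTTAAGCAGATCGGCTTTAGTTACTGTAGCGAGGA
GCGTTATGGAGCGCGCCGTGGTCGTCCGAAGTGCTATAGACTATAGAGAGTTATGAACGTGGAGGTTCGACCAAGACCCC
GGAAGTCCTAGAGGATGCCTAGCTGTAGTAGTGCAAGGTCCCCTTGCTATCTAATTGCAGTAATAAGACGGAGGTGGGGC
>peak_chr1_187552_187775
GAGCCACCCCTACCTGAGTGGAAAAGCGAGCGGGACAATTAACTACCATACTTATGTTATTTCTTCGGCGCGTGATATCC
ACGTATGCACAGGTCATGTATTGAGCGGATAGGGCGGGACGGCTGCGTCAGGATAACTTTAGAAAGCCCAAGAATTACAT
GCGTTATGAGTTTGATCTCTAGTCACTTGCCGAAGTAACGAATGGCCCTAAGCCCGCGAAGGACGGACTAGAGGCTGTTA
TAACGGGCGTCTTGACGCTACCTTTAAGGCTATGCGGAATCCATAACAAAATGCGTCAACGCCCGGAGTGAGTAACAATT
TCACACCCAGTGCTTCTGGCAAACTCTGAGGTACTAAGGCCTGAAGGGGGTTGACAATATAGTGGACTGGTCCTGCCTTG
>peak_chr1_133829_134063
TAAGTGAAGTGACTTAACCCCCGAGTTGTACGAACCGTGTGGAGGCGGTGCAATGCTACAGTATTCCGCCACGCCCAGCT
AGGTAGGAGGGCGGGTTTCCGCACACATGCTGCCCTAGGTAGTCACCGATTGGGTAATGGTAGTGGTCGGGATGAGTCTG
TCTAGGCTTCAGAGCGGATCGTAAGTGAAGTGCAATAGGATTCAGTTTTTTTTTTGTTTTTTTTGTTGGCCTTTCATCGT
ACCAGCCATATACATGCAACGTCGTCCCAGAATGAACGACAACTAGGACGAGGACCGGGGACTCCGAGCCCATCTGAGAT
CCCCTAAGCTCCTTGCCACGACATTAGTTATTTAAGGTTTCCGCTTCCTTTTGAGGAGGGTTCCGGATCAAGTGGGTAGG
>peak_chr1_153503_153737
CCGAACGAGGATCCCAGATGCCGTGCCCTGACACCGAGCCGCGCCGGCAAAGTACCTATATATAAGTGAAAAGAATAAGT
GAAGATCATTTACGACGCTCTCCTAGGTGGTATCCAGACGGGATGCGTCGCCGCCTGGGTCTGTACATAGAAACCAACGG
GATATCGTTCTGCTATCATTAGCAATTATTTTTTTCTTTTTTTTTTTTTAATCCTGTCCCTCTGAATACGGACGTACCAC
CTGCTGGTTTCTCTGCCATACCAGATTCGTCAGGGAAAGTTAGACATTCTATGCGCCGTGTTTCCTTCCGGCCTCTAGCG
CACTCCTGTACAATCAGTCAAAGCTAGAGAACTTTTGATGTTGTTTACTGTTAACCCGTATACCGCGCGGAATAGCTCCA
>peak_chr1_23840_24073
TAACCTAGCAGGTCCGTCTTACGATGGGTATGGATTCCGGCTCGTCGACGCTCTGAGTATCCAGTTGTGGTATATTTAGA
TCCGATATACTGGTTATCCCAACTGAGACAATAAATCTCGGGGCGCCTTTTGTGTTTAACTATAACTAATCGGGATCCGC
ATCCATTATATCACCTTCATAACCTTTTTTCTCTTTTCTTTTTATTCGAACGTTTAATGAAGCTCCTTGAGCGGCCATGG
GATTGGCTCAGAGGACGCCTCCTTCGAGACTCTTTCTTATATGGGTGTGAAGAAACCCCAGAAAGCGTCGTGTCCGCACC
AATACTTTGTTATAAGAGCCACCAGCGTGCGTGAGACCAGTTCGTATTGGTTCTAATCGCATGATCAAGGAACGAAGTTA
>peak_chr1_134855_135082
AACGTAGAGCACAGTTTACAAATAACCGTTCCTTGTCGAGCACGGATTAGGAGCGGATAGCGGTGTAAGAGTGTTTACAA
TGGGCACTTATACTATTGTCCTGGCTCTACAGTGGCAGGTAAGCGTCCGGGGGTGCCGCTAACAAGTTTACGAACTTCTA
GTAAGGTCGCAAATCCCCTCCCATCCACTGGACGTCGTGACTATGGCTGTTGTTGTGCGCAGCATTTCTCAGAGTGGCAC
GTACCAACTTTAGAGCCGGTCCGCATTTAAGTACTCGACAGTTTGCCAGGTAAGATTGTCAAAACATCTTCATAATGAGG
TCCGATCACCGGGGCTTCAGAATAACTGCTAACCTCGCGGACGGTGGTCTACTCAATAAAAATTAAAGATACCTCCGGCC
>peak_chr1_92549_92790
GATGAGGGTCGTTCTTACCGAAACGTTTAGGCGGCGAGCTCCACGATTTGAATCGACCACTCTATTAGCATTCTCTTTCA
GATCAATCTTCCGTTTATAAAGGAACAGACGAAAAAGGGTGTTGTCCGGCGGTGATCCCGTGGTGTCAAGCTCCCTAACA
CTAGTTATTGCTTCCGAATTCCATTAAAATTCGGAGAGCACCCGCTGCCCTAAAAAGATTAGCTATGAACCTATCGTAGA
CTGGAGCACCCAGGATCGGACTATGTGTGCGTCTATGCGAGCGGTTTAACGAGCGTTCGTGATAGTGGAAGACATCGGAT
TCAAGAACGTAAGGAGCGTGCCGTGCATTTTGACAGGAATGCATGACTCACGCTGTCAATCTTACACCTAGCTATCTTGA
>peak_chr1_15383_15628
GTTAACAAAACCCGGCTGCCCGAGTACGCCAGCACTCCCCAAGTCTGTAGGACTTCCAATTCATATTCGGCGCATGGGGT
TTAACGCCGCCTGCTATTCGGATACCACGACCAGTATGAAAGGGTAGTCACATACATCCTCCTAGCCGTAAAGGCAGATT
TTTTTATGTCGCTCTTTGTATTTTTTTTTTTTTTTTTTTTAGCCGCGGATCTTGCGCTAGTAGAATAATTAAGTTTGGAC
GTCGGCACCCGCGATAGCCTGCCACTGATCATAGCATCTAGGAATTGGTTTAGCCCACGGGAATGAGGCATGTCTTAAGC
GAACTCCCAAAGGTGAGTGGCCCATTATGTCGGTATATTAAGCTCGGGAGTCTACAGCTAGGCCGTACCAACTAGTTTTC
>peak_chr1_173173_173406
TCACAGTGGGAGACACACTGCCGGAGCGCTCGAGTAGGCAAAGCGGGTGCGCTTTCCCCCGTGGGAAGTAGGCAGTGCGG
TATTGAGACCCCGAACACCGTAACCGTCTTAGTGAACTCCAAAGATTCAACTGGTTTTGTCGTATAGAGGCTACTATCCA
GGGTGCAGTGATCGATCAGCCAACCTTCCCGTGATTAGCCATCCGATTCACCGTCTCACGTTACTTCGGAGAATTTGTTC
TACCACCTACCAGAACACTGCTCCTTAAATTCTCAGAATTTAAAAAGAGTGACTACATCATTCCAGGGTTGGCAGGCCAC
TTTAAGGAACAGCCCTAGGACATCACAGTTGATCAGTGTGATACTACGAGTTGTAGATGTGGTACAAGATATAGTCTTGA
>peak_chr1_204423_204651
TCAGAGTGCTGCCAGCTTTCGTAAACAGAGGGATTGTCCTTTCGACCGCCCGATTAGAAGAACGGCTCAACACCGGACAT
AGGGTTGTTAAAATACTTGGAGAAGAAGGGGCTGCTCAAGGCAACTTCATTACTTTGGGTTAGTTATAATTTCTGAGTCG
GAAGAACCGCGAGGGGGTTAGGTTTTGTTTTTCTTTTTTTTTTCTGACCTAGTAGCAAGCGACTGTGTCATAATACTCAG
AGTGCGAGAGGTCGGGCCGTCGCGAGCTTCCCGAGGTGATTGGGCACCCCGGTTCTGTAGTCCGCGGAGCAGTCCTATGG
CCAATGCCCTTTCGTCATAGAGGCAAAGCGATAGTGATGCGGCTAGAACGCATCACTTTTACTTCAGTGAGAGTGCTCGT
>peak_chr1_8463_8707
TATATCATAGCGTTATTGACACTAAGCTCTTGTTACTACTGCAATCGGCTGACGCACCGGAGCGCGCCGCTGTTTTACAC
ACACTCGCACCCGCGAAGTATAACGGTTCTAGGTCTCAGTTCTCCAACAAGAGTCTACGGCAGTGCCGATATGAATGCAA
CCCGGACCGCAAGCAGGTCCGTCCGCTCAGATGCCCGTTGTCCACGGCGGTCGCTCAACCTCTCAGTATTAGTGTATACC
GACGATATCCTTGTAGGTAGCCTGCAATCTCTCGTTCAACTTATTTCAATCGATACCCTCTCCAATTGCGCCCCGAGATG
GAGCAGAGTATTCAATGCCTGTCCCTCCCCCATCATCCGGCCAATCCTGTGCGGTATACACACGAGCTGGACAAAAGCAC
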