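>RT|synthetic
GCTTCGTGTTATTAGTACGCTACTAACGGTGGCCTACACAGGAGGCCAACCGTTGATTTTAATAATCGAACATAAGCCTA
TAAACAGGCCTATCCAGCCCCCGATGCCAACCTAAAATGTGCCTGATGTCTGCGTGGAGTAGAGACGTCGCGTACCTAGA
ATATGAGACTTATTAAAAATAAGGGCCCTCCCGGAGTACGTTGCACACAGGATGCTGTACGGGGGCACAACGGTCTGGAG
GACCCGGCTGCGCAGTAACCCTTGGACTAACTAGAGATGCCCGCCGTTTGGATAGGGAGC
>RH|synthetic
GCTCCTATGCCATCAAGCTTTGTTCACTCTAACCCCGTCCTAGCAAACTTACGCGTATCCACCCTTTTTACTGTGAGAAC
TGTCATTCCAGGCAATGCGCGACATACAACATGCTATGGCAACGTGTAAAAATGGTTGAGAATTGAACGCGGATTGTTGG
AGAGCTATTCGGTTGTATGCTCGCCTTCGTGCCTTATCCGGTGGATGTCCCTGGAACCGTGACCATGGATATTGGCTGCC
>INT|synthetic
ATGGCATACGTATCCTGTCACACATCACATCTGAATCGGGGGACGATTTATGGGACGAGCCTGGACTGGCCGTCCGATGT
TGGTCATTATCGGCAGGCAGTAGACCTCCAGATGTCCCTAGTGAAGGACTAGTAACTTCGGGCTCATAAGGAAGCAGCAC
GGTCCGATTACAAAACACCGGCGCAACGGGATATAACTCTCCTTGATCATAATGCTCCTCTCGTGCTAAATTACCCAACA
TCAGGGTGACCCGCCGCGGGGGCCCGTATCCACGTTACCTGGGCGCAGATGATACCCCCC
>TRANSPOSASE|synthetic
CTCATAACGGGGGGACCCCCCCACTATAATCAAACGTTTCTAGTGTTGGAATAAGGCTTCCCGACTTACTGGTTCTGTTA
CCGGTGTCCCCCGCCGCCTTAACGATATGTGAAAGGCGGGACAAATAAGATCCCGACTATGGCACGCGCACAGCCATTCC
CTGTGAGAGGTCTGGTTTGTAATTGATGTATTCCGCGTGGGATTGTATAAGAACATAGCCAGGTAGCCGTCATTAACCTA
ACCCTTCAACAGTTCCTCCACCTTTCGATAGGATCCTAGCCCTAAGTCAAGGGGCGAAAA
>rDNA_18S|synthetic
CTACTTGCTACGTTTCCGTCGCCTGGTTTAGAGTAAATCCGGAACGTGCGTCCTTAATATGACAGGCAGTCCTCACTTAA
GTTGTCCCCTACCGCGATCATATGAACTTAGTCTCTCCCTGTGCGTGGTTAACATAGGGTGCAGCGGGTGGTGGCCGATA
GTCACATATCCCGCCATCTACCAGTTTGATGAGAATAATTTAGCACAACTTGTAGAGTTATACAAATCTTGATTCCTTAC
GCTATTGACCCTGATATCAATCTGGCCTTGTCATAGCTTTCTAGTGTGCTTGGTATGATTGGCAGAGGAGGCGGCCCTGA
ACGTCGTCAACAATCCGCGAAAGGTGTATCTCGCGTCGCTGATGAGGTGTCGAAGAGACCCGACCGACAATCGGATCACC
TATGGTCTCGGAAGAACTGCTCCTCTCAATCGTCTTGGCAGTGTGAGCGAGAGACGTATACATGTCTTGCATAAGAAAAC
GGGTATCCTCGTGTACTTGGACTGTGGTTTTGCCTCGCTTATCAGTAGGCCACGAGGGTCTACTGCCTCGTGTGCATGGA
GTTTGACATCGCCAATCATTGTAACATCAGTTGAGGATATTTTGACCACGGCGGGACTCAAAGAGTAAATTCTTTCTTCG
AGGGATTCATTTATGATCCCTAGCGAACACCTGAACGGGCTAAAGCAAATGCGTACATCGCGCGGGCAATATACCGTGCG
TTACTCGTTACGGGATCCAACCGAGGAGGAAGGTCCCCAGTAAAATGTTAATCTCAATGCATCGTGTGAGATATATGCAA
CACGAAGCCAACTCAGGAAATTGCCTGACGAACACATCCGAATAAAGGTAGAAGCGTTCATACCGTATGAGAAGATCTCA
GTACGTACCGCCCCAACGCTGGACGAGTTAGAAAGCACCACCATAACGAAATCCCCGGAGTGGAAACTGGTTAGGCGAGG
TCATAAGTCATCTGCGGTGTAGTGATAGAACCTTCCTAAAGCTAATTGGTTGCACTCCAATTGCTCTTACTCAGTGAGGG
CCCGAGATTCCGTCTGGCCACTTTCCCCCGGTAAGGGTGATACCTATAGTTATACCTCTATACCTCATCCCCCCCAGTGT
GATAGCTTCGCGAGAAGCCGTTAGACGTGCCACTGTTGGGCTTTAATTTGCGGCCTCGCCAAGAGCAAATCCACGTCGAA
CTTCATCATCCATCAAGCGTGTTTAGGGCGAAACTGGTCCCGATCCTAATTGAGGGGCTTAAGGGTGTTCTTGGTAGCCT
CCATATCAATACGCCCCTTCCAACCTATAACGAGTTCAGACCGAACGCGTTAACCCGGCGACCGGGATCACAGCGTGGTT
ATAGCCGGGGCGGCAGACTTCGGGTGGCGTTGAACAACGCGAGCATCTTACAAGTTCAGGTGCGGATCAGAAACTTAGCT
ACGTACAGAAACAGTTATCAACCCTAATACGAACTATATTGAAGTTATTGCCATCTTCTAAGACGTCTGGCCACCGTTAC
TTGTGTCGAGGGGTAAGAGACGGCTACAAGAGCTCTAGGGATGACCTACGTAATTGTATACTATACCATCAGACTAAGCG
ACTCGTGGAGAGCAGCGATCACCAATTCGGACACGGAGTACAAATTCAAGGCAGCCGTCGCTATAGCTTACAGCACGTTT
ATACGATTAGCACGCCAGTAGTTGGCATTCTAGCATGCAATCAACCAGGTGCTTCATATACTGGGTTACCGGTCCCTAGT
ACCTCCTCATGTTTAATATTAGAAAAAATCGGTCACTTTCCGAGACAAGGA
>rDNA_5.8S|synthetic
GCGTCGTAGTCTCGTCAGATCAGAACCTGCCAGCTGCCTGTGCCATTACTTTCGATGTCCGCACGATTGATCCAAACCCC
TCACGAACCTACATCCTGTTCATCCGAGTGTTCCATCAATAAGCCCGCCCCAGCCTGAACTCACTCCTGGAACAAAAGAA
GCTCATAC
>rDNA_26S|synthetic
CGGTCGGTGCCACACGTCGGGGTGCCCAGTGTACCTGGAGGGCCTCTAACAGCTATGCCTAGAAGGATGCATGCGAAACA
GCCCTAAGGCTGTTAGTACCGCCTTATTGGATATTGTACAAAAGTTACAAACTAAGCGGCATCAAGACCGACTTCTTCCC
TTGATACCCCCGTCCCGGGTACCTTGCCCTCCACCAACAACGACGATTTTGTGTCCCGTTCTAGTGGCATAACGGGCTAT
ACTCGCATGATATTACTGTCGACAGTACCCTCCACGAACACTGGCGTTGAACGATGGCAGCGCATTAGTGGTCAGAAGCT
TTCGCAAGCTTACAGATTTTACGACATACTATATCCCACAGGCGTGAATGAGCCTGAATGGTGAGCACGAATCACAAACG
TGCGTACTAGATACTGCGCAACTTGGGCCGCTTCCACGCGTCGCGGACCTTTCGGACTCCGCCCTAAGCGACTCTAGTAC
CCCTACGGAGGTTCTACAATGAGTGCCTATTGGAAACTTCGGCCATCCCGTACAACCTCTCGTACCCAGGTACCTTACCG
AATTCGGCCGGTGTTAGCAGCGGGTTAGGCGTTACCTCGCAAGCTCATCTCGGACAAACAGCGCCTCCCTCCCGCAGATC
AACCCAGAAGAGGCCCACCGTATGAAGCCTTATTACTGCACTCGTATAAGGAAACTGAGGTGGCTTCCTCAGACGTGTTT
GCCAAGTGTCCCATGAGTCAACCCAGACATCCAGAGTAATGTTGAGTCGAGGATCCAGATTATGTATATTCTCGAGTAAG
GTCTCCCTATATTTCCCGCTCGAAAACTGGTACAAACGTCATTGCGTCATGCTCGGTGTGTCCTAGTCTTGTCACTCAGC
GACGGGTATTGTTAACTGCGATAGACTGCAAGTGATATCACCCCTGCCAGCTTTCCCAAAGCTTTCCAGGGGGCGAACCA
ATCTGAAGTTCGCACGGATTGCTTTTGTCGGTGGGTCCAAATACGAAAAAAGATATCCTATTTCAAGAATACGAAACGGT
TCTAGGCTGTCCGGGCTGTGTGTGCGCTGCGGTAGATATGAGGGGACCCTCAGCGAGCCCACTAGATTGAACATCAAATT
TTCGCTAGAAGTACCATGCTGTAATGCAATTATATCTGCAGCATCCGTGCTTTCCGTGAATCTAGGTGACCACGGGAACC
GACTGGGGGGCTATGCTGGCGATTAGATCACGTTCGAGCTTCCCGGTTATCTAACAATCGTCGAATGATCGCAAGACGTG
ACCAGGGGATTACATTCGGATTTCATGGAAAGATTCTAGACCGTTGTGGACCCATCCATTCAACGGTCACAGCTCTGTGA
AACTGTTTTATAGGACTGTGTACCGGATCTTTGTTGGTCACTACGAATGGATGGACACCGGGATCAGATAGCCCGTTATG
TACTTTACATCACACAAAAGGGCATATTCTACCGCCCTCGAAGCGTCCCCGAGACGGTATAGAGGCAGATTGCGTAACTA
GTAGCGGAAATGATTAGCCACCGTGCTCTTGTGTCACGCCAGTACCCAAATGCGGCCCTTGGAATCAAGAAGAAGGTATA
CGGGTCTCGTATTAGTGCTAAGTCCTTCGAGATACATGGTTAGGGGTAAGGTATCTGAAGATTAGCAGGGGATATAGGTA
GCAACAAGCTTCTGCGATCAAGGGACATTGGCTTGTGCATAGGACGTGATGACTTATATAGCTTTACGCCGCAACTCGCT
GCACTCTGGAGTTGTGGAAAGCCCCCTCTGTATGTGTGCCTCGAACTGGGCAACAGCGTTAATTACTTCATCATAAACAG
CTATAGTTACGAAGCATGCAGTTATCCCTAACTCTGGTCTTTGTTATTGGATACCTATCAACAAAACATCCTGAAAATGG
CCTATCCGCCTTCTTATCGTCTCCTAATATGACGGACAGTCGGCAGCGAGGGCTCGCATGTTTACGTGCCCTTAATAATG
GATGTCCTCTAGTGAAGCATAGGAGTAGGCAGAGAATAGTCTTAATGGGTTAGCGAGACAGTGACGAGTAGGGCCTCACT
CCTCTATTCAATCAGGGCTGTATGTTTGCAGTCGACTGCCCGGAGACGTACGCGTTGAATTCGCAGCCGACAGGGTACCG
CTGGAGACAAGCGCAACGCCAGGGGCCTGGGGCCGCTAAGGGTTAGCGGTCACATTGGCACCTCCCGGCCACCGCCTCGC
GGGAGGGGTTATAATCGACCAGGATTTGGCTTGCTAGCTGGGTGGAACTTTCGGCTATGCTCGGGCGGGCAACTTTAGAG
AGACTCTGCTGTCAGAATACGACCGTACAACCAGAGTCTGGTCGTTTCTTTGCAGAAGGGTGCTAGCTAAGTCAGGGCGC
GGTGAAAAAAACCGCACTCTTCGTCGAGGTGTATAACACGAATAGCACGGACTTTAGACTTATCGCCGAACCGATTGTCG
TGCTGCGTGTTATTTGAAATATTTGGCGTGATGACAACATGACTAAGTCCGACCTTGGTGGGGAGACTGCTATGTACGCT
CCAATAAGTGGTTGAGCTGATCTTGGGGTTAGTTAATTAGGACCCGTGCAACGCACTAGGATGACCCTTGTTCCTTATGG
AAGGGAAAGTTAACCGTCAATGAGGTGTGATGAGTTGATTTCGTGCACGAGATTACAGGAACGCATCGTGCGCCATAGTA
TTTTAAAGTTTCTGATACGCATGATGGGCTACACCTATCCTAGAGGGCGGGTCATTCCCCTCCGAATTAGTGTAAGCGGG
ACGTGCGCTAGGGTAGGGGGTATCGAGCATCAGTTGGTTGACTACCAACTTCACGTCGGTGCCAGTACCTCGCCACATGT
GTCGCAGAAGTGTCCTTCACAGAGAGTGACGTCCTCCGACGTACCATTTGAGATTCAACGGACAAATCCATTTTACTAGT
GGTGGCGTTTTGCATGCCAACCGTATAGCCCGGTAAGACATAGACTGCCTCTGTAATTCACGATTCGCGCTGTAGGCACA
CGAAGAAATCACAAGTTGAAACTGGTTTAAGGCGGACTACCAGTTGCAGCTTACGTGCTAAAGAACGTTGGGTAACGCTT
TTCTCGGTTCTTACTGTCATATAGTCCACTTCTTACAAATTTTGCCCTCGTAATTCACGACTTTGCTCGGGCCTTACTGG
TTAAATCCGGCGCCAATGAATTAGCATAACCTGGTTGCGAGTCAGGCGAATAAGCCAAGTAATTAGGTTGCATAGAGTAC
TGTTTGGAGTCACCGGGCGTTTCGTCCTGGGACCCTTGACGTCATCACCCTTCCCAATAACTGGCCTTAAGTTTAATCGG
AGCTACGATCTGATCAGATACCCGTAGCAAAGGTAGATGCGTTTGGA
>rDNA_5S|synthetic
TTGGGCAAGGAGATGTCGACCGTCGCCTGAGAAATTATGGAACGCGGTGCATGCTAAACGGGGACGCTGCTACCCGGAGG
GTTTGAGAAGAAACGTTGACTTTGTTAGGCTCGGGGATTACCAGTCTCTACGTTGTAATGGATCTCGTCCCCGCTGGTAG
GATTGGATGGACTAGGTGAG
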