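>chrW
AGCAAGTCCAATTTAATCTCCGAAATTCACTAAAATGGTTCACTCTGAGGTTCCCTAAAAGACCCCCACC
CGACACAGTTCCAATACGTGGTATTCAGTTCGTCCTATTTATGTTTTAGAACCCAAGGATTAACTAATTG
TATCGGTGGGTGCATGTTACGTACCGTAGCACCATCTCTACGATGACACAGGTCATTGTGAACGGTTATA
CGTTATAACAATCACCTCAAGAACGATATCCACCATAACAGATACAACAGCTAAAATAGTGTGAAAGTGG
AATTCACCTCTGTGTTAATCCAGATCGAACCATGCTTATAAGCATACTTGAATCTATTTTAATTAAATTC
GACTATCAAACGATGCCCATTATGTTGTACGAGTTTGCTCCCGCTCACGATATACAAAGTGGGACGTGGG
CTGAGATGGATGTGCCGGGATGTACATAAATCATTTATAATACGACATTCCCCGAGTTCGGATCTTCTAT
ATGCTTACGTTATGTATGACAAAAAAGATAATTGCTAATGCCGGAGAGATTAACAGCCCCTTAATGGTTC
TCATACCTTCAGCCTGCAATTTGAGCTATGAGCGCGTTGTCATCCTTGAGATCCTTTCGCAACTGTACTC
CGCATAAGGATGCTGCGAAAATGCTAACAGATTATAATGCAAAATGGAGCATAGATCCATAATAATTTCG
ACGACAACTTGCCAAATAGAAGCTGACTAACAACTCGCTTTTCTATGCTCCGTGCAGGTCCGCACGCTCC
CCGTACATTATATGATGGGAAAAGGAAGTGTGGAATAGGAAATTCAACACCTAAACGTTTCGTATGTTAT
TTCAGCAGGCTCGAAGGAGAATATGAGACCGGCACGCGGGTGATTGCAGTGTCGTATAAAGGACTTTATC
TTATGGAAGTTGATCAGTTAGGCAAAGAACCGTTAGTGTGCTTAGCGAGTTTTCATTTATTAATACGCGT
AGTAATATCCTCACCGTAATTTTGCTTCATTCCTCTTGCCGCAGCAAAGGGAGCTTATCTTTATCGTGCT
AAGGTAACGTCGCCGATGATGGACCGGGCAATGGATCTCTTAAGTGCGCAATTAGTCATGTATCTAAAGC
TCTAATTTGAGGCTCTAGAAGCGCATAGACAGAAGGAATTATAACCAATTTGGCGAGCGTTACTTGTTTC
GATATTTCTTCAGACCGTTCTTTAAGATCTATTCTCTTAGTAGTTGACTACCACTTCGAAACTGATTAAC
AAGTACGGAATCCTAGATTTTATATTCCTCTTGAAAGTGGACGACGTGCGGGAATAAAATGCTCATGGAG
TTAGCAAAGACCGTATAGGATTTGCGCCGTACCGATCGAATTTCACTACATTAAGGCCACATGAACCACT
AACTTGATCCAGCGTCTGGAAGGTCTAAAATCTCTGAGTCAAGACGTTCCTTGGCGGCTGTATTGTTCCG
CAAAGTTTCTGGTTTAGATGACAACACTTGAGAATAAAGGGGGTTCGCAACCATGCTACGAATTATAGTT
ATGCGAGGTAGCCCTCGTTACAATTAAATAGTGTTCTTGTGAGAAATAAGTATCCTACCCTAAGCATCTA
GATAAGCATATAATAGTTAACACTGGCAGGCCCTCAGTATGACTACCTATGGCATCACAGGATAGATATA
TAAGCCTGCATAAAAAGATGTCCAGCTAAAGACTCCTCACTTGCGTCTTATTCTGGTATCACGATTGGCT
AGGGCGATTGGCTTGGTAATAAATGCCCTGACATCTAGCTAAACAGAACGGAATGGTATGTGCCGAGTCG
TGAGCCAGGTCGACTCCAAATCTATTGTGAAGAATTATGTTAGCAATCACGCACTCAGTCGTCGAAGAAT
AAGTGTGCAGTTCCTAAAATAGGACAATCTGACATGAATTCATCATGTGTATAATCGCGTCCAAATATTG
CTGGATGGTTAATTTGGGAACATTGATACCACACCGATCA
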