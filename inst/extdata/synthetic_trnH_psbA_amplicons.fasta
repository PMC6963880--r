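>synthetic_schinifolium_trnH_psbA synthetic stand-in amplicon (543 bp, PleI cut at 436)
GTTATGCATGAACGTAATGCTCAGTCCGCCCAGGTTTAGTTTGCCTCACCCTGGAATAACTGACGCGGTC
CTGGCGTGACAGAAGGAAACGTTCCTCATAAATAGAGGAGGATGTGTTGTCGTACCAGCTGGCGCTACCT
CGCTCACGATGGCCTACACTTTTGTATCGGCCGAGTTCCTCTACATTCGGATACAGTAACCGTAGGAAGG
AGTTACCGCACTACGGACGTCAAGGGCACCTACGGGAAGAGGGCACATATAAGTTTCCGGGGCGCGGCCG
GATTGATTGATCCCCAAGTCCCCAACAGAATCTTCATAGTGAACCTAGTTGAAGACCTAAACCATCGCAC
TTCCCAGGCCCGGTCGTGGACGGTACAACCTAGGGACTGCGTATATCAGAGGCACAGCCGATGTGATTAA
TATGCCGGAGTCTGGGGGTCGGAAAAATTAGGCGACTTGCAAGCATCATGCCGTCCTTGGAGTAGTACCC
GCCCGATTCCCAATCTCTCACGCCATCCTCGGATTGTGAATCCACCATGCGCG
>synthetic_piperitum_trnH_psbA synthetic stand-in amplicon (562 bp, no PleI site)
GTTATGCATGAACGTAATGCTCAGATAACGTGACAGAAGTTTGTACAGCTAACAGGGTCCTTCAGGTTAA
CCACTGTCGGCGTATTGTACCCACTTAGAATGCCTCGGCTTCGCATGCTATAGTGTACCGGCAGGTTTAA
CCCAAGGATAAACCGCTAACCCAGCCTGGATGGTGATCTCCTAGAAATTGCGGTCGTGAGTGAATCAATG
TGCCCGCAAGCAAGATGATCTAACAGCCGTGCTTCATCAGGATCGTGGGAGTTTGAGCGGGATGGATAGC
CTAGAGCTTATTTTTCTTGGAGTTAGGTGTCAAGCAAACACGGATCCACACGGCAAAAATTCTTCTATAG
GTAACCGGGTCAGCAAAAGACGCCCCTGATGTGAATGCAACGGCCACAGGCTGGCCGAAAATTACGTGTA
GGGCCAAAGATTATTAAATCAGGAGACTTACTCACCTAAGCGACGTTATGCCCGGTAACGACCACCAGCA
GATAACCAATATTTCCAAGATCAGCCTGACGGCGAGGAGGCGCACTTTCGGATTGTGAATCCACCATGCG
CG
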