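name	forward	reverse	min_product	max_product
ZanID1	GATTCACAATCCACTGCCTTGAT	GCTCATAACTTCCCTCTAGACCT	513	533
ZanID2	GTGGGTATCCTTAATTCTCTCATC	GATACTCTCTTCAGGGTAATTCCA	547	662
ZanID3	GGAGGGATCAAACTTCTGGAAC	AGAACCACTATACTATCACGGTCA	576	691
ZanID4	GATTTGAGCAAGGAATCCCCATTTG	TCTTCATTTTGACCCGATATTCAA	573	712
trnH_psbA_universal	GTTATGCATGAACGTAATGCTC	CGCGCATGGTGGATTCACAATCC	NA	NA
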