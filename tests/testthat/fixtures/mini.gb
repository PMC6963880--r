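LOCUS       MINI0001                 120 bp    DNA     circular PLN 01-JAN-2020
DEFINITION  Synthetic miniature plastome fragment.
ACCESSION   MINI0001
SOURCE      synthetic construct
  ORGANISM  synthetic construct
FEATURES             Location/Qualifiers
     source          1..120
                     /organism="synthetic construct"
     tRNA            1..75
                     /gene="trnH-GUG"
     gene            complement(80..110)
                     /gene="psbA"
     misc_feature    join(115..120,1..5)
                     /note="origin spanning"
ORIGIN
        1 gctaaagaca attacataac atacacgtca gcacgaaact tgttggccca gtgtgaatcg
       61 cttaagggtt aagtaagtgt gatgcatacg cctttacttg ctgtgtccac cccatcggac
//
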