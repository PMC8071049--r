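LOCUS       ctg1                   20000 bp    DNA     linear   BCT 01-JAN-2026
DEFINITION  Synthetic example genome for format documentation; generated, not
            derived from any real organism.
SOURCE      synthetic construct
  ORGANISM  Synthetica exempli
FEATURES             Location/Qualifiers
     source          1..20000
     CDS             100..400
                     /locus_tag="SYN_0001"
                     /product="hypothetical protein"
     CDS             complement(1200..2100)
                     /locus_tag="SYN_0002"
                     /gene="nifB"
                     /product="nitrogenase cofactor biosynthesis protein NifB"
     CDS             2500..2900
                     /locus_tag="SYN_0003"
                     /gene="fdxN"
                     /product="ferredoxin III"
     CDS             3100..4300
                     /locus_tag="SYN_0004"
                     /gene="nifS"
                     /product="cysteine desulfurase NifS"
     CDS             4400..5200
                     /locus_tag="SYN_0005"
                     /gene="nifU"
                     /product="Fe-S cluster assembly scaffold NifU"
     CDS             join(6000..6400,6500..6800)
                     /locus_tag="SYN_0006"
                     /product="hypothetical protein"
     gene            7200..7800
                     /locus_tag="SYN_0007"
                     /pseudo
     CDS             8100..8400
                     /locus_tag="SYN_0008"
                     /product="hypothetical protein"
//
LOCUS       ctg2                   12000 bp    DNA     linear   BCT 01-JAN-2026
FEATURES             Location/Qualifiers
     source          1..12000
     CDS             300..1100
                     /locus_tag="SYN_0101"
                     /gene="nifH"
                     /product="nitrogenase iron protein NifH"
     CDS             1300..2700
                     /locus_tag="SYN_0102"
                     /gene="nifD"
                     /product="nitrogenase molybdenum-iron protein alpha chain"
     CDS             2900..4300
                     /locus_tag="SYN_0103"
                     /gene="nifK"
                     /product="nitrogenase molybdenum-iron protein beta chain"
     CDS             5000..5600
                     /product="hypothetical protein without locus tag"
//
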