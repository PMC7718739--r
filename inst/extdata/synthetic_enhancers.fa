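>minWT_synthetic
GAACTGGAGTCTGTTCTCGAGCGGCGGAGAACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCA
TCCCCATCTAGGTAGAACACTTCTCCTGCAGCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAA
GCACTTTCGGGAAGTGCCTCCTTCATGACAGTGGCGACCTCCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATC
TGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGGAGGGAGAAGCAATGATTAAGCTC
CGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGG
CACGGTTGAGTCAAAGCTGAAGATTCCAATGAACGATGATGAATCGTCTGTGTAGGACATATCCACACCGGTAAACAATG
TTCT
>extWT_synthetic
GTACACAGGCTCTCTCTACGGCCCTGTAACTCAAATGGAAAGTTCTGCGTGAACTGGAGTCTGTTCTCGAGCGGCGGAGA
ACCTTAAACCCGACAGAGAGATGATCTAAAGGTTATCAAGGTCAGGTCCATCCCCATCTAGGTAGAACACTTCTCCTGCA
GCGTTTGATGACCCCTTTTTGTGGTGCAGCCAGCACTAAGGCGAGTAAAAGCACTTTCGGGAAGTGCCTCCTTCATGACA
GTGGCGACCTCCTCACCCGTCGAAGAACCAACTATAACTGCCGGAACATCTGATACTCACCGAGAAATTCCATTCACATT
AGCATAATAAAAGGAAGTTATACTTGGAGGGAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGC
CAATGATTACTTCTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGGCACGGTTGAGTCAAAGCTGAAGATTCCAAT
GAACGATGATGAATCGTCTGTGTAGGACATATCCACACCGGTAAACAATGTTCTGACGGGCCAAGTTACGGCCGTTTTTA
TCGGCTCTTAACGTTAAGAGCCTGTCTGGTATCAGCTGTGTAAGTGTAGCATGGGTGGTTTACAGCTGGTCCTCTTATGT
AACCAATGAATCGCAGGTGCCCTCCGACTATTTGGGACATGTTTAGTCTTGTAGAATCCACTAGTGTGGTAACCGTACAG
TACATTGGGGATCAGTGCAGATAGCATGCCGAACAGCGCGACGGACAATCTCGCTCTCAAGGACATCTCAAAGTTTCG
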