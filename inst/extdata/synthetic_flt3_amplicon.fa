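>FLT3amp_synthetic
CTGTGAATATGGATGACCCGGGGGGATATGGCCTAGGTCCGACCGACATCCCGAGAAAGCTAATTTGCAAATACCCGCGT
CTGAGACACTCCTTATTATCAGCCTACGCTAACAGCCCAAGATACACGTTTGCGAATGCCGGCGGGCCTGATTGCTGGAA
CCCCTCAGTTAACACGGACGCGCAAAGGATTAAGCTTAATTATCCATTGGGATGTGCTTGGTACTTCCTGAGAAGGGGTA
TAACAGAGTGGTGCCACGCCGCACGACTGGATGAAAGTTCGAGACGGATCAGTGATGATTCAGCTACAATCGCGACGTAT
AATGCCAGCTCTAAAGGTCCGGTTGAACAAATCCGGGCAGTTTGCCGGTTATTAACTTTTGATTCATTGAACGGGCCAGG
CGCATCTCTAACACACTCCGCGTGGGCCCCGGGGCCGCCCGTATTGTATCCTTATGAACCCATTCACGCCCGCAGTGCAC
GACTGTCTGCCGGCCGATGCTTCGTAATCCCCCATTCCGCAGATCTGGAAGATAGTTCATTAAGAGCGCGGCCTTTGCAG
ACCTTATGAACCGTACACGTTGAGACCCACAGACGCTAAACAATGGCCCCGGCTTGTGAGGTGCACCTTGGATTAAGGAT
GCGGATATAAGGTGTGGTTCTTTCGCTGTAATATTACTAATCCTCCGCGTTCCACAGTTTTTCGTTTATCCGGGCCTCAC
CCGGGGTGTCCCTGTTACGGAGATATGCACCATGCAGTAACATAAACTTCCAGATATGCTGTCCCCCTAGCAGGAGTTAT
T
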