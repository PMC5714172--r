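>short_end_fragment 96 bp Hsmar1 transposon-end EMSA substrate (pRC919 XmaI fragment, printed sequence)
CCGGGCTGCAGGAATTCTATTAGGTTGGTGCAAAAGTAATTGCGGTTTTGGATCCCAAGC
TTCTTCTAGAGGTACCGCATGCGATATCGAGCTCTC
>long_end_fragment 162 bp Hsmar1 transposon-end EMSA substrate (pRC919 SacII/AccI fragment, printed sequence)
GCGGTGGCGGCCGCTCTAGAACTAGTGGATCCCCCGGGCTGCAGGAATTCTATTAGGTTG
GTGCAAAAGTAATTGCGGTTTTGGATCCCAAGCTTCTTCTAGAGGTACCGCATGCGATAT
CGAGCTCTCCCGGGAATTCGATATCAAGCTTATCGATACCGT
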