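>synthetic_NM_001140642 synthetic stand-in template carrying the published myoglobin assay binding sites
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGA
GAGAGGTCACAGGGATAGGAACCCCCTGCACGCAACTGGAAACTTACATTTGAAGCAGCC
TAAAGTACAATGTAAATTCTAAGTGCTGGTTTGTAGGATATTCATCCCTACACTGTATAT
GCCGAACGTTCTAATAAACGACTTAGCAACAAG
>synthetic_NM_001171862 synthetic stand-in template carrying the published myoglobin assay binding sites
TCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGA
TTGCTTGTGACTTCCAGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTAC
TGGAAAAGTGTATGAGGCAAAGCTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCG
TCGAATGTGCGTTGTTCCTCTGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACA
CACTAGTCGCCCTTGAGAGCA
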