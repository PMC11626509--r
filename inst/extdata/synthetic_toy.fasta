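>SYN_TOY.1 synthetic toy transcript
AAAACTCCAATGGTCCAATCAACACAGACGGTTCCACGTGCTGTCTTAAAGCAGCGCACA
ACGATCAGGTCTCCAACTCGAAAATTAGGTATGAGTCAAATTAGCCTCCATGGTTCGACA
TTGCATCCTAGGCGATCTTTGACTGAAGCTACCCAACACGTGGCGCGTGCTTCCTCCTTC
GCATTAGATCCGTTCGACAATGGTTACAAATCTATGGTGAACACAAGGAGTTATCGGTGC
CCATATAGCACCCGGCTAACGCGAGAAGTTTCTCGAGATTTCCCTCAAGTGCCTTCTGTT
AAAGACTAATATATGCCGAACGTTCTAATAAACGACTTA
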