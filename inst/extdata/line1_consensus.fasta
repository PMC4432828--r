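>LINE1_consensus_amplicon bisulfite-space LINE-1 consensus amplicon (printed in reverse-primer orientation)
AACTATAATAAACTCCACCCAATTCAAACTTCCGACCACTTTATTTACCGACTCAAACCTAACAATAACT
AACACGTCCCCTCCCCCAACCTCACTACCGCCTTACAATTTAATCTCAAACTACTACGCTAACAATAAAT
AAAACTCTAATAAACATAAAACCCTCTCAAACTAAACGCGACATATAATCTCCTAATATATCATTTACTA
ATCGCATTAAAAAAACACAATATTAAAATAAAAATAACCCAATTTTCCAAATACCATCTATCACCCCTTT
TCTTTAACTAAAAAAAAAAATTCCCTAACCCCTTACACTTCCGTACTAAACATACTCGTACTTCACTCAC
ATACACCCACTATCCTTCACCCACTATCTAACACTTCCCATTAAAATAAACCTAATACCTCAAATAAAAA
TACAAAAAT
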