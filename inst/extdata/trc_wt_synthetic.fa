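>trc_wt_synthetic synthetic 224-nt stand-in for a Trc promoter+RBS wild type (not the real sequence)
GAGCCGCCATAAGCTTATTTACCGGCACCTTTGACAACCGATGATTCGGGGTAAAAAGTG
CGACGGCTAGGAGCATGCATGTGCCACGAACTTAATTTGCTAGAAGTAACGGCCTATGCG
TATCAAAGACTGAACCATGTCCGTATAGGGGGTTAGGGAATTAGTTACACAGTGCAACCT
AGAAAAGAGCTTAACTGTGCGATGCCAGGCCAGGGTTGCACGTG
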