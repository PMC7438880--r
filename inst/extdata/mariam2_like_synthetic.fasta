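>Mariam2_like synthetic consensus (generated, seed 20260922)
AAGTTGCCATCTATTTGATGAGGAGAGCCAGAAACCGTCTATTCAATTGAGTATTCTCCAGTAAATCGAC
TGTAGGAATAAAAACCGACCGGCAATGCACGATTGAGGACAGGTAGAGTCACGTGCGTTGCCACGAGGCC
TCTGTCCGAGGCCTAGGAATGCTCCCTTTAATTAAAGAGGTGCACGCACTTACAATAAACTAGTTCCAGA
CCTTACGCTGCTCAAACGCAGTAATTGTATCGCCGTATACTCAATATTCTCAGCGCTTACGAATGCACCC
GGATACTATCT
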