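>Mariam1_like synthetic consensus (generated, seed 20260922)
AAGTTGCCATCTATTTGATGAGGAGAGCCAGAAACCGTCTCCGTATATTTCTCCGCAAAACTGGCGTGAC
GCGTACTGTACGTTAGGGCTTCGGTGTGCATGTAAGGGAGGCATGAACGATCTTGCCCGTCAGTAAGGAG
TTACGTAAGCTCCACCGCCTTGAATTAGGCTCCCTCCGTTACTCTCAGTGTCGATGAGAGCATATACGTT
GGGACACTGGTCAGATGTACATTCCGAACGCGTTCCTGATGCCGTATACTCAATATTCTCAGCGCTTACG
AATGCACCCGGATACTATCT
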