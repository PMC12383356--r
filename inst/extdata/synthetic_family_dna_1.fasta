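>seq1 synthetic dna homolog
GGATCATAAAGTTAAACCACCGATGCTGAGCACGAGTACGTACGTAAAGAGTTCGCTGTA
>seq2 synthetic dna homolog
TGATCATAGAGTTAAACCTCCGATGCAGAGCACGGCATAAGACGGAAAGACTTCGGGGGGCTGTA
>seq3 synthetic dna homolog
GGATCATAAAGATAAACCACCGATGCTGAGCGGCGTACGTCGGAAACCCTTCCCATGTA
>seq4 synthetic dna homolog
GTATCATAAAAGTTAATCCCCGATACTTAGCACGGCATATGTCGGAAAGACTTCGCTGT
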