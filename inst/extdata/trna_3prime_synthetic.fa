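>Lys-tRNA-synthetic
GATCGCGATCCATACGACAAAACGTATAGTTCACCA
>Arg-tRNA-synthetic
AGAACAATCACAAAGCCGCGAGCCAGTTTTCCCCCA
>His-tRNA-synthetic
GCTTAATTGCTTAACTCCTGATCTATACCAGTTCCA
>Gly-tRNA-synthetic
GAGAGCAGTACGCTTACACTGGCTTCCACCCTGCCA
>Leu-tRNA-synthetic
ATTTAAAAAAAATCACACTGTCCGGTGATAACCCCA
>Pro-tRNA-synthetic
CCGGATAGCCTCCCTCTTCAAAACCTGGTGACCCCA
>Ser-tRNA-synthetic
AGCTCTCCTGCGGCGAGTTATGGCTGGTGTTACCCA
>Trp-tRNA-synthetic
TGGTCTGCAGTCGTGCTCAGGTGAATGTGCGTCCCA
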