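>moR21_sponge_gblocks published moR-21 sponge gBlocks oligonucleotide (7 bulged sites, XhoI/ApaI flanks)
ACTAGCACTCGAGCCGATCCGACTCCTGGTACAGGCGTTCCGACGTATGGTACAGACGCT
CCGACCATTGGTACAGTCGATCCGACGTCTGGTACAGACCGTCCGACGCATGGTACAGCC
GGTCCGACCGCTGGTACAGACGATCCGACCTCTGGTACAGACGGATCGCGGGCCCTAATA
TC
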