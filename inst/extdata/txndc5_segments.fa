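>txndc5_wt wild-type Txndc5 3'UTR seed-match segment (reconstructed from published mutagenesis primers)
TGAAAAGAAAACTCAAGTGGTACAATTTGGTTTATACTTTCTAA
>txndc5_mut1 seed-match mutant 1 segment (as published primer Mut1F)
TGAAAAGAAAACTCAAGTGGTTGAATTTGGTTTATACTTTCTAA
>txndc5_mut2 seed-match mutant 2 segment (as published primer Mut2F)
TATGAAAAGAAAACTCAAGTGACACAATTTGGTTTATACTTTCT
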