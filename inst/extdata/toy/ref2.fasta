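>hydra
TCGGTCGAACATACTGTATAGATGGGCTTG
>A1
CCAGTCGACCGTACTGTGTACAGTGGATTG
>A4
CGAGTAGTGCAACATGGGTAGAGAATATAG
>A3
CGAGTTTAGCAAATTAGGTAGTGAATATCG
>A2
CCGGTCGAGAATACTGGGCAGAGTTTATAG
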