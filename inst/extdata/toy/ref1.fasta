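>hydra
GTTCGGGTAGATATGTCATACAAGCTGGCT
>A4
AGATGTGTCTTCTGCCTATTACTATTTTCG
>A1
AGCTGTGTCTTGTGCCTATTACTATATTAG
>A3
TGCTGTTGGTTTGGACTAATATTGTTCAGT
>A2
AGATGTGTCCTGTGCCTATTACTGTTTTAG
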