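>B5
AGACGTTACCTGTGCCAATTACTATTTATG
>B3
GGACGTTACCTGTGCCAATTACGATTTTAG
>B1
GGACGTTACCTGTGCCAATTACTATTTTGG
>B6
CAAGCGTACCTGTTTCAATCATGTTTATTT
>B2
CGACCCTAGTTGACTCAATTATGGTTTTTC
>B4
CGACCCTACATGTGCCAATTATGTTTTTTT
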