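references:
  - name: ref1
    alignment: ref1.fasta
    tree: ref1.nwk
    outgroup: hydra
  - name: ref2
    alignment: ref2.fasta
    tree: ref2.nwk
    outgroup: hydra
query:
  alignment: query.fasta
  tree: query.nwk
positions: [1, 2]
alpha: 0.05
quantile: 0.95
seed: 7
outdir: out
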