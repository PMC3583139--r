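(B5:0.12542566,(B3:0.18908884,B1:0.03528761):0.03400059,((B6:0.18549615,B2:0.21441377):0.08192664,B4:0.00414275):0.19247701);
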