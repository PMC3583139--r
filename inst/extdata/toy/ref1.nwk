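(hydra:1,((A4:0.05557799,A1:0.0827409):0.04694985,(A3:0.66945445,A2:0.03357631):0.01902184):1);
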