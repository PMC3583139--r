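(hydra:1,(A1:0.24895221,((A4:0.04744302,A3:0.36590531):0.18962234,A2:0.07723946):0.19157577):1);
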