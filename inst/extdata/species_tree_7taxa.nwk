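((sp1:0.5,sp2:0.5):0.5,((sp3:0.25,sp4:0.25):0.25,(sp5:0.25,(sp6:0.125,sp7:0.125):0.125):0.25):0.5);
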