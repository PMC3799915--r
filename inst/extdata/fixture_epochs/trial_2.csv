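-0.25,1.75,-1.5,0.5,2.5,-0.75,1,-2,0.375,1.25,-0.5,0.625
2,-1,0.25,-0.375,1.5,0.75,-2.5,1.125,-0.25,0.5,-1.25,1.75
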