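0.5,-1.25,2,0.75,-0.5,1.5,-2.25,0.25,1,-0.75,0.125,-1
1.5,0.25,-0.5,2.25,-1.75,0.5,1.25,-0.25,-1.5,0.75,2,-0.125
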