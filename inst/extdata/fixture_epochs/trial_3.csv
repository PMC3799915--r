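1,0.5,-0.25,-1.5,0.75,2.25,-0.5,1.375,-1,0.25,0.625,-2
-0.5,1.25,2.5,-0.75,0.25,-1.125,1.5,-0.25,0.875,-2.25,1,0.5
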