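organ,brain,liver,kidney,small intestine,lung,remainder
brain,90.0,0.1,0.05,0.02,0.3,1.2
liver,0.1,45.0,1.5,2.0,2.5,1.1
kidney,0.05,1.5,110.0,2.8,0.8,1.3
small intestine,0.02,2.0,2.8,65.0,0.4,1.4
lung,0.3,2.5,0.8,0.4,50.0,1.0
remainder,1.2,1.1,1.3,1.4,1.0,8.0
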