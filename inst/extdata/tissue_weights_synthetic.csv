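organ,weight
brain,0.10
liver,0.20
kidney,0.15
small intestine,0.25
lung,0.20
remainder,0.10
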