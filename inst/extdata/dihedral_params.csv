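pair,mult,k,delta
generic,1,0.2,0
generic,2,0.2,0
generic,3,0.2,0
generic,4,0.2,0
G*,1,0.08,0
G*,2,0.08,0
G*,3,0.08,0
G*,4,0.08,0
P*,1,0.5,0
P*,2,0.5,0
P*,3,0.5,0
P*,4,0.5,0
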