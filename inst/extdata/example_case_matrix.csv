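state,A,B,C,D
A,0.23,0.22,0.26,0.28
B,0.23,0.24,0.21,0.32
C,0.13,0.58,0.13,0.15
D,0.15,0.24,0.42,0.19
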