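d_um,efficiency
0.1,0.99
0.3,0.99
0.5,0.98
1,0.97
2,0.93
3.2,0.88
5,0.78
7,0.66
10,0.52
15,0.35
20,0.24
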