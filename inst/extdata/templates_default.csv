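1,0.5,0,0.085714,0.171429,0.257143,0.342857,0.428571,0.514286,0.6
1,0.75,0.5,0.25,0,0.12,0.24,0.36,0.48,0.6
1,0.833333,0.666667,0.5,0.333333,0.166667,0,0.2,0.4,0.6
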