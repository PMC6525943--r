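# origin -2
0.35355339059327379
-0.70710678118654757
0.35355339059327379
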