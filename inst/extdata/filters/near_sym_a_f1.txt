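# origin -3
-0.088388347648318447
0.35355339059327379
-0.53033008588991071
0.35355339059327379
-0.088388347648318447
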