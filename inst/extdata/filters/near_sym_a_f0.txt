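# origin -3
0.1325825214724777
-0.53033008588991082
0.22097086912079608
1.7677669529663693
0.22097086912079608
-0.53033008588991082
0.1325825214724777
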