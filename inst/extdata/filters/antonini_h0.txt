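# origin -4
0.037828455506995456
-0.023849465019379991
-0.11062440441842335
0.3774028556126538
0.85269867900940333
0.3774028556126538
-0.11062440441842335
-0.023849465019379991
0.037828455506995456
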