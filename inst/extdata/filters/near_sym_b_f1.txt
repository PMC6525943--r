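# origin -7
-0.0043062592207482753
0.0095823536736343567
0.031719309086636026
-0.10683581854648373
-0.020331735956966628
0.45080685546612315
-0.72126940900438974
0.45080685546612326
-0.020331735956966687
-0.10683581854648377
0.031719309086636026
0.0095823536736343567
-0.0043062592207482753
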