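# origin 0
0.00057966507168909155
-0.0052802308317138665
-0.0039322174542003865
0.05678270303606054
-0.056882607351007759
-0.12438888013141346
0.30426060160870999
0.72564554215795996
0.58300467829676983
0.020650498412401401
-0.13075800983145036
0.034625709765075965
0.015694099078782945
-0.00039509196551792541
-0.0048594282327476335
-0.0005334692563032054
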