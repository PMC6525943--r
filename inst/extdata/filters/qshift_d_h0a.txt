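# origin 0
0.0026366379052562851
0.0014484299804140273
-0.01938908139293638
0.0041514769498796102
0.073643821125855907
-0.085468918027733654
-0.1109163017551888
0.30305757921221504
0.73264938875850472
0.56618565055757364
0.044423182275981958
-0.14010735349655878
0.010118976687351013
0.055564448772377817
-0.023632244478081162
-0.0021435912141441883
-0.0024275979401918182
0.0044190584525198914
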