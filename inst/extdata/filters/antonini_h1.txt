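# origin -4
-0.064538882628938435
0.040689417609558416
0.41809227322221226
-0.78848561640566439
0.41809227322221226
0.040689417609558416
-0.064538882628938435
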