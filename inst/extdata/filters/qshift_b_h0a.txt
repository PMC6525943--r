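# origin 0
0.0032531424613242202
-0.003883211269808368
0.034660350444669405
-0.038872800124450789
-0.11720388955421504
0.27529538202128123
0.75614564363052672
0.56881042301183926
0.011866091305967266
-0.10671179998437635
0.023825380742626703
0.017025220206662493
-0.0054394751325462795
-0.0045568953867083156
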