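# origin 0
0.0015000707495762503
-0.0039178010958758726
-0.10544038553509483
0.23364975369077295
0.79580687841585229
0.54341840403692754
-0.0023831386636559049
-0.072791309831950451
0.017623356219869612
0.0067477343866735847
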