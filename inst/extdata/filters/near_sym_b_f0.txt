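# origin -9
-0.0014844898610283448
0.003303309472119082
0.0074079724038369956
-0.028981954046966203
-0.0045326344436035461
0.12020612490102368
-0.026304622604665887
-0.20505069733245984
0.37846716509873318
0.92815321519911687
0.37846716509873335
-0.20505069733246023
-0.026304622604665564
0.12020612490102359
-0.0045326344436035547
-0.028981954046966182
0.0074079724038369921
0.003303309472119082
-0.0014844898610283448
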