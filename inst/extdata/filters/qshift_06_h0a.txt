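# origin 0
0.035163838790339005
-1.2321373187544011e-09
-0.088329420365521702
0.23389031932440779
0.76027236851474134
0.58751829876793182
-3.3109247519820215e-10
-0.11430184054320755
-1.9354851578989151e-17
-5.5236609619335238e-10
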