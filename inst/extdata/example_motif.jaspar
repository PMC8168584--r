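>MA0000.1 SYNTH_ETS
A  [  2  1 17  1  1  2 ]
C  [  1 17  1  1  1 16 ]
G  [  1  1  1  1 17  1 ]
T  [ 16  1  1 17  1  1 ]
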