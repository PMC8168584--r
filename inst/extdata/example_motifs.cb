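>AP1_like_synthetic
2 1 1 16
1 17 1 1
17 1 1 1
1 1 1 17
1 1 17 1
2 16 1 1
>SOX_like_synthetic
1 14 1 4
14 1 4 1
1 1 1 17
1 1 1 17
1 1 17 1
14 2 2 2
2 2 2 14
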