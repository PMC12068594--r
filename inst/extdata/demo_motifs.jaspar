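>DEMO1 synthetic_paired_box_like
A [ 12  2  0 14  0  1  3 ]
C [  1  0  0  0 13  1  2 ]
G [  1 12  1  0  1  0  8 ]
T [  0  0 13  0  0 12  1 ]
>DEMO2 synthetic_hmg_box_like
A [ 14  0  0  1  9 ]
C [  0 13  1  0  2 ]
G [  0  1  0 13  2 ]
T [  0  0 13  0  1 ]
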