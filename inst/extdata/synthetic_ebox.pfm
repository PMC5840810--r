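>synthetic_ebox
A [ 12  3 85  2  1  4  3 30 ]
C [ 30 80  2 86  1 86 10 20 ]
G [ 28  5  4  3 90  2 70 25 ]
T [ 22  4  1  1  0  0  9 17 ]
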