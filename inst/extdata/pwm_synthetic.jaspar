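>SYN0001.1 SYNFOS
A  [  2  25   0   0  28   0   1   3 ]
C  [  5   1   0   0   0  27   0  20 ]
G  [ 18   1  28   0   0   1   0   2 ]
T  [  3   1   0  28   0   0  27   3 ]
>SYN0002.1 SYNKLF
A  [  0   1   0  22   2   0   0   1  19 ]
C  [  1   0   0   2   0  24   1   0   3 ]
G  [ 24  24   1   1  22   1   0   2   1 ]
T  [  0   0  24   0   1   0  24  22   2 ]
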