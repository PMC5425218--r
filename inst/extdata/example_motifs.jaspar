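>MX0001 KLF4
A [ 12  2  0 90  3  1 80  4 ]
C [  3  90 2  2  1 90  5  6 ]
G [ 80  4  2  4 92  5 10  4 ]
T [  5  4 96  4  4  4  5 86 ]
>MX0002 GRHL3
A [ 85  5  2  3 88  2  4 90 ]
C [  5  2 90  4  4  3 88  4 ]
G [  5  3  4 89  4  5  4  3 ]
T [  5 90  4  4  4 90  4  3 ]
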