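0000	1
0001	0
0010	1
0011	0
0100	0
0101	0
0110	1
0111	0
1000	1
1001	0
1010	X
1011	X
1100	X
1101	X
1110	X
1111	X
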