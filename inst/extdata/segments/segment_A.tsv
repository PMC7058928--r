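0000	1
0001	0
0010	1
0011	1
0100	0
0101	1
0110	0
0111	1
1000	1
1001	1
1010	X
1011	X
1100	X
1101	X
1110	X
1111	X
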