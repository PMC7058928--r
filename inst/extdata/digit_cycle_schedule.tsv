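0	8	0000
8	16	0001
16	24	0010
24	32	0011
32	40	0100
40	48	0101
48	56	0110
56	64	0111
64	72	1000
72	80	1001
80	88	0000
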