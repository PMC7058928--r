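x1	INPUT	-	P_Tac
x2	INPUT	-	P_Tet
g_up	NOT	x1	-
g_down	NOT	x2	-
out	OUTPUT	g_up,g_down	-
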