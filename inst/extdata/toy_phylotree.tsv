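haplogroup	parent	variants
H	-	2543G>T,10162T>C,13559C>A
H1	H	150A>G,12263T>G,12711T>C
H2	H	1720G>A,6602G>A,9374T>G
H3	H	6073A>T,7045C>G,15726C>G
H11	H1	4885A>C,4946G>C,14352T>A
H12	H1	2928A>C,4150G>C,16188T>A
H13	H1	13347A>G,15357G>T,15521T>G
H21	H2	8768G>A,16228A>C,16520A>G
H22	H2	3365T>G,3574A>T,15386T>C
H23	H2	3063C>A,7787A>T,15254T>A
H31	H3	6703C>G,9759A>C,13929T>G
H32	H3	4613A>G,12293C>G,15624T>A
H33	H3	7742G>T,7831A>C,11042C>T
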