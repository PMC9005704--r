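family	superfamily	order
accord	Gypsy	LTR
412	Gypsy	LTR
blood	Gypsy	LTR
Blastopia	Gypsy	LTR
mdg3	Gypsy	LTR
gypsy	Gypsy	LTR
Gypsy-2_Dsim	Gypsy	LTR
ZAM	Gypsy	LTR
Invader1	Gypsy	LTR
Invader4	Gypsy	LTR
copia	Copia	LTR
Copia	Copia	LTR
roo	Pao	LTR
297	Gypsy	LTR
17-6	Gypsy	LTR
Tabor	Gypsy	LTR
Transpac	Gypsy	LTR
Doc	Jockey	LINE
Doc6	Jockey	LINE
jockey	Jockey	LINE
BS	Jockey	LINE
BS3	Jockey	LINE
BS4	Jockey	LINE
Ivk	I	LINE
I-element	I	LINE
F-element	Jockey	LINE
Rt1a	R1	LINE
Rt1b	R1	LINE
G2	Jockey	LINE
X-element	Jockey	LINE
hopper	hAT	TIR
pogo	TcMar-pogo	TIR
P-element	P	TIR
1360	P	TIR
transib1	CMC-Transib	TIR
transib2	CMC-Transib	TIR
S-element	TcMar-Tc1	TIR
Bari1	TcMar-Tc1	TIR
hobo	hAT	TIR
INE-1	INE-1	TIR
FB4	FB	TIR
Kepler	TRIM	LARD
LARD	LARD	LARD
THARE	LARD	LARD
Helitron1	Helitron	Helitron
DNAREP1	Helitron	Helitron
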