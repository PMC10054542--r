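residue	particle	atoms	type	area	energy	units	radius
ALA	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
ARG	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
ASN	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
ASP	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
CYS	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
GLN	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
GLU	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
GLY	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
HIS	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
ILE	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
LEU	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
LYS	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
MET	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
PHE	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
PRO	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
SER	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
THR	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
TRP	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
TYR	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
VAL	BB	N,CA,C,O	P5	70	1.2	kcal/mol	2.3
ALA	SC1	CB	S_ALA	60	-0.31	kcal/mol	2.3
ARG	SC1	CB,CG,CD,NE,CZ,NH1,NH2	S_ARG	60	1.01	kcal/mol	2.3
ASN	SC1	CB,CG,OD1,ND2	S_ASN	60	0.6	kcal/mol	2.3
ASP	SC1	CB,CG,OD1,OD2	S_ASP	60	0.77	kcal/mol	2.3
CYS	SC1	CB,SG	S_CYS	60	-1.54	kcal/mol	2.3
GLN	SC1	CB,CG,CD,OE1,NE2	S_GLN	60	0.22	kcal/mol	2.3
GLU	SC1	CB,CG,CD,OE1,OE2	S_GLU	60	0.64	kcal/mol	2.3
GLY	SC1	HA2,HA3	S_GLY	60	0	kcal/mol	2.3
HIS	SC1	CB,CG,ND1,CD2,CE1,NE2	S_HIS	60	-0.13	kcal/mol	2.3
ILE	SC1	CB,CG1,CG2,CD1	S_ILE	60	-1.8	kcal/mol	2.3
LEU	SC1	CB,CG,CD1,CD2	S_LEU	60	-1.7	kcal/mol	2.3
LYS	SC1	CB,CG,CD,CE,NZ	S_LYS	60	0.99	kcal/mol	2.3
MET	SC1	CB,CG,SD,CE	S_MET	60	-1.23	kcal/mol	2.3
PHE	SC1	CB,CG,CD1,CD2,CE1,CE2,CZ	S_PHE	60	-1.79	kcal/mol	2.3
PRO	SC1	CB,CG,CD	S_PRO	60	-0.72	kcal/mol	2.3
SER	SC1	CB,OG	S_SER	60	0.04	kcal/mol	2.3
THR	SC1	CB,OG1,CG2	S_THR	60	-0.26	kcal/mol	2.3
TRP	SC1	CB,CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2	S_TRP	60	-2.25	kcal/mol	2.3
TYR	SC1	CB,CG,CD1,CD2,CE1,CE2,CZ,OH	S_TYR	60	-0.96	kcal/mol	2.3
VAL	SC1	CB,CG1,CG2	S_VAL	60	-1.22	kcal/mol	2.3
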